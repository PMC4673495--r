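---
title: "geckoevo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geckoevo: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geckoevo)
```

`geckoevo` packages the comparative-genomics procedures behind three
adaptive traits of geckos — adhesive setae, nocturnal vision/olfaction
and tail regeneration — as reusable, tested functions. This vignette is
the package's own account of the underlying models: what each procedure
assumes, which parameters matter and why their defaults were chosen,
what the synthetic-data generators do and do not emulate, and where the
design was genuinely open.

## Protein physicochemistry

The setae β-keratin classifier rests on four physicochemical quantities
plus a motif scan.

**Composition fractions** are counts over the 20 standard residues;
unknown residues (`X`) are excluded from the denominator, so fractions
always sum to 1. **Molecular weight** uses average (not monoisotopic)
residue masses plus one water — setae β-keratins are described by their
bulk (~10 kDa) size, which is an average-mass statement; `X` contributes
the mean residue mass, 111.1 Da. **Isoelectric point** is the root of
the Henderson–Hasselbalch net charge over the two termini and the D, E,
C, Y, H, K, R side chains, found by bisection on `[0, 14]` to `1e-4` pH.
Net charge is strictly decreasing in pH, so the root is unique and
bisection cannot fail. The pKa set is an EMBOSS-style table (N-terminus
8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
Y 10.1). No primary source for gecko work states a pKa convention, and
published pI values cannot be reproduced exactly without knowing one;
only the basic/acidic side of the pI > 7 criterion matters for
classification, and that is insensitive to the table choice. A peptide
with no ionisable groups at all (possible only when the termini are
excluded) returns the neutral convention value 7 with a warning rather
than failing, since such a chain is neutral at every pH.

## The five-feature β-keratin classifier

A protein receives flag 1 when its best ungapped window identity against
the 20-residue setae core box (`SEVTIQPPPCTVVVPGPVLA`) is at least 70%,
flag 2 when Cys > 10%, flag 3 when Gly > 15%, flag 4 when pI > 7 and
flag 5 when MW < 15,000 Da. Flags 2–5 are strict inequalities, exactly
as printed in the source classification; flag 1 is inclusive (≥ 70%).

"Sequence similarity" is interpreted as **ungapped percent identity over
the motif length**, maximised over all windows; when the sequence is
shorter than the motif, the motif slides across it and the overhang
counts as mismatch. The motif is short enough that gaps are unnecessary
at the 70% scale, the denominator convention makes deletions in the
subject count against it, and the scan is fully deterministic — ties are
resolved trivially because only the maximum is reported. A gapped
Smith–Waterman mode (`method = "local"`) is available behind a switch
for sensitivity analyses but is not the default. Whether the original
criterion counted conservative substitutions as "similar" is not
recorded anywhere; identity is the reproducible choice.

## Trees, placement and expansion dating

Tree inference here is deliberately **distance-based** (p-distance or its
Poisson correction, then neighbor joining with midpoint rooting): the
original analyses used maximum likelihood, but at the scale this package
targets NJ on well-separated families recovers the same groupings and is
exactly invertible on additive matrices, which makes it testable to
machine precision. Negative NJ branch lengths are clamped to zero with a
warning (standard practice). Maximum-likelihood and Bayesian inference,
relaxed clocks and bootstrap support are out of scope.

Subgroup assignment (olfactory-receptor Class I α/β/ε/ζ/δ vs Class II γ;
opsin paralogs RH1/RH2/SWS1/SWS2/LWS) is by **nearest labelled
reference**: the query takes the subgroup of its closest reference, with
support reported as the margin between the best and second-best subgroup
mean distances. An exact tie between subgroups returns `"ambiguous"` —
never an arbitrary winner.

Expansion dating is the **minimal strict-clock reading** of "calculate
the divergence value of the branch site": each node's depth is its mean
root-to-tip path length (substitutions/site) within its own subtree
(i.e. the tree is ultrametricised by averaging), a single linear rate is
fitted through the origin by least squares over the calibration nodes
(depth on age), and every node age is depth/rate. Interval calibrations
(e.g. a 51–66 Myr window) contribute their midpoint by default, with the
endpoints available by configuration. Dating is scale-equivariant:
multiplying all branch lengths and the rate by a constant leaves ages
unchanged.

Bursts are maximal runs of node ages (sorted descending) whose
consecutive gaps are at most `max_gap`, with at least two members;
isolated ages are reported as singletons. The default `max_gap = 5` Myr
is chosen because reported setae expansion episodes sit about 9 Myr
apart edge-to-edge, so 5 Myr separates them while tolerating within-burst
spread. How the original burst windows were delimited is not recorded;
the package fixes this one reproducible rule and does not attempt to
reproduce specific published window edges.

## Pseudogene scanning

A candidate gene model (exons in 0-based half-open coordinates, listed
in transcript orientation) is spliced against its contig,
reverse-complementing minus-strand exons. The ORF scan flags a lost
initiation codon (first codon ≠ ATG), premature stops (1-based codon
indices strictly before the last codon), a lost termination codon, and a
terminal frameshift when the length is not a multiple of 3.

Against a functional reference, exons are paired by an
**order-preserving best-identity assignment** (dynamic programming;
exon rearrangement is not assumed, matching how collinear exon maps are
drawn). A reference exon with no partner at ≥ 50% identity is *missing*;
a matched exon covering < 80% of the reference is *incomplete*; internal
alignment indels of length ≢ 0 (mod 3) are *frameshifts*; and an exon
whose cumulative coding offset is not a multiple of 3 is *shifted*.
Neither threshold is recorded in the original analysis; both are
configurable (`identity_floor`, `coverage_floor`). Start/stop loss is
assessed *relative to the reference*, so a defect shared with the
reference is never charged to the candidate — this makes the identity
comparison (a gene against itself) unconditionally clean. A candidate
with no alignable exon at all is flagged `"unresolvable"` rather than
being given a verdict. Only the standard nuclear code is supported.

## The Ka/Ks screen

The selection screen replaces branch-model maximum likelihood (`codeml`
free-ratio) with **pairwise Nei–Gojobori (1986) counting** — this is the
package's one prominent, deliberate methodological deviation. The
screen's contract is preserved: a gene whose focal-vs-comparator ratio
exceeds 1 is a positive-selection candidate. NG86 details: fractional
site counts per codon from the nine single-nucleotide neighbours
(changes to stops are nonsynonymous; `s + n = 3` always), sites averaged
over the two sequences, multi-hit codons averaged over all minimal
mutational pathways with equal weights (pathways through stop codons
excluded; if every pathway is blocked, all are used), Jukes–Cantor
correction of both proportions, `pS` or `pN ≥ 3/4` flagged `"saturated"`
and `Ks = 0` flagged `"Ks_zero"` instead of producing infinities. With
multiple comparators a gene's statistic is the mean of its defined
pairwise ratios.

Upstream of the estimator, `filter_blocks()` plays the role Gblocks
plays in genome-scale screens, simplified to a **codon-column filter**:
a column is dropped when its gap fraction exceeds 0.2 or its modal-codon
frequency falls below 0.5, and surviving runs shorter than 3 codons are
dropped, so the output is always frame-valid. The original
false-positive filtering step is unrecorded; the screen exposes only the
ratio threshold (default 1) and a minimum of 30 compared codons, and
logs every exclusion with a reason.

The expression overlap counts a candidate as upregulated when any
post-autotomy timepoint (1, 3 or 7 days) reaches at least
`fold_threshold` (default 2) times its day-0 value; a zero day-0
baseline counts as upregulated iff any later value is positive (a
documented convention — the fold is undefined there). The original
"upregulated" criterion is unrecorded; 2-fold from the day-0 baseline is
the conventional choice and both are configurable. Ids absent from the
table are excluded from the denominator and logged.

## Synthetic data: what it emulates, and what it does not

Every generator takes a mandatory integer seed, restores the caller's
RNG state, and returns its planted truth alongside the data.

* `simulate_family()` runs a forward-time birth–death process (rates λ,
  μ per lineage per Myr over `time` Myr), prunes extinct lineages and
  evolves protein sequences site-wise Poisson at `rate`
  substitutions/site/Myr, with motif columns scaled by a conservation
  factor `c` (0 freezes the core box). Substitution is equal-rates over
  the other 19 residues — deliberately non-biological (no JTT/WAG
  exchangeabilities, no indels), but sufficient for testing a classifier
  that depends on identity fractions, and for generating divergence
  gradients.
* `simulate_burst_tree()` builds an exactly clock-like duplication
  history with internal nodes at prescribed ages, which is what makes
  the dating tests exact rather than statistical.
* `simulate_codon_pair()` is a mutation–selection **rejection walk**:
  nucleotide proposals with transition bias κ, stop proposals rejected,
  nonsynonymous proposals accepted with relative rate ω; time is scaled
  so one unit ≈ one substitution per codon site for the average sense
  codon under the configured process. It is not a GY94 matrix
  exponential, but the realised synonymous/nonsynonymous counts are
  returned, which makes it a valid oracle for the estimator regardless
  of the process details.
* `simulate_gene()` + `inject_disruptions()` build intact multi-exon
  ORFs inside synthetic contigs and mutate them with exactly the
  requested defects (start/stop loss, 1-bp frameshift insertion, exon
  deletion, exon-boundary shift), mirroring the truth record.
  Frameshift insertion is implemented for plus-strand models; splicing
  itself is strand-complete and tested with mirrored minus-strand
  coordinates.
* `simulate_expression()` draws log-normal day-0 baselines
  (`meanlog = 3`, `sdlog = 0.8`, i.e. typical transcript-abundance
  spread) and multiplies each planted gene by at least `fold` at one
  random post-autotomy timepoint; with `noise_cv = 0` the planted
  fraction is recovered exactly.

Because the generators are idealisations, a passing suite demonstrates
that the *machinery* is correct — planted signals are recovered, oracles
agree, thresholds act exactly as printed — not that the thresholds would
reproduce any particular published gene inventory on real proteomes,
which depends on unpublished sequence sets.

## Fixture sizes and numerical choices

The test and acceptance fixtures are sized for desk-scale runs: 100
random peptides for the pI oracle, 200 random pairs for the motif-scan
oracle, 200 replicates of 300-codon pairs per ω for estimator recovery,
20 replicate ortholog sets of 50 genes (5 planted at ω = 3 vs background
0.2, t = 0.3 substitutions/codon) for the screen, and 10 replicate
3-exon genes for disruption completeness. Ortholog fixtures default to
**500 codons per gene** — the typical length of a vertebrate single-copy
ortholog CDS; at that length the planted (ω = 3) and background
(ω = 0.2) Ka/Ks distributions are cleanly separated at t = 0.3 (over
1,000 simulated genes per class the planted minimum ratio was 1.23 and
the background maximum 0.30), so planted-truth recovery tests measure
the screen, not generator shot noise. At 300 codons a planted gene
occasionally realises a near-neutral substitution pattern that no
estimator could flag.

Other numerical conventions: bisection tolerance `1e-4` pH; NJ negative
branches clamped to 0; burst segmentation operates on ages sorted
descending with a strict gap rule (`diff < -max_gap` starts a new run);
premature-stop indices are 1-based codon positions (R convention);
alignment of exons uses Needleman–Wunsch with match 2 / mismatch −3 /
gap open 6 / extend 2, and identity is measured against the reference
exon length so truncation is penalised.

## Known limitations

* Pairwise NG86 is less powerful than branch ML and mildly biased at
  high divergence; the neutral mean is calibrated (within [0.9, 1.1] at
  300 codons) but individual pairs scatter widely.
* The strict-clock dating contract cannot express rate variation across
  lineages; calibrations in serious conflict with the clock simply
  produce a least-squares compromise (inspect `fit_rate()$points`
  residuals).
* The exon comparison assumes collinear exon structure; genuine exon
  shuffling would be misreported as losses.
* The family simulator evolves no indels, so classifier tests never
  exercise alignment-gap behaviour of the motif scan beyond the
  sliding-overhang rule.
* Absolute pI values depend on the pKa convention; only the
  basic/acidic classification is convention-robust.
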