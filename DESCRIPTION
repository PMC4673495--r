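Package: geckoevo
Title: Comparative Genomics of Gecko Adaptive Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of comparative-genomics procedures
    for studying adaptive-trait evolution in geckos: physicochemical
    profiling and core-box classification of setae beta-keratins, distance
    tree construction with fossil-calibrated dating of gene-family expansion
    bursts, ORF-disruption scanning for opsin pseudogene detection,
    reference-placement subgroup assignment for olfactory receptor and opsin
    genes, and a pairwise Nei-Gojobori Ka/Ks screen for positively selected
    genes with regeneration-expression overlap. Includes generators for
    synthetic gene families, codon-pair alignments, disrupted gene models
    and expression tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
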