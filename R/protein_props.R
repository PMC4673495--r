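# Physicochemical profiling of protein sequences: residue composition,
# average molecular weight, and Henderson-Hasselbalch isoelectric point.
# These are the quantities that the setae beta-keratin classifier
# thresholds (see classify_keratin).

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

# average (not monoisotopic) residue masses in Daltons; free water added
# once per chain. 'X' (unknown residue) contributes the mean residue mass.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 111.1
)
MASS_WATER <- 18.01524

# EMBOSS-style pKa values. Only the relative ordering around pH 7 matters
# for the pI > 7 basicity criterion, so the exact table choice is a
# documented convention, not a fitted parameter.
PKA_TABLE <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)
PKA_NEGATIVE <- c("Cterm", "C", "D", "E", "Y")
PKA_POSITIVE <- c("Nterm", "H", "K", "R")

# normalise to upper case and validate against the amino-acid alphabet
.aa_check <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    stop("sequence must be a single character string")
  }
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence is empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  seq
}

.aa_chars <- function(seq) strsplit(.aa_check(seq), "", fixed = TRUE)[[1L]]

#' Fraction of a residue in a protein sequence
#'
#' Composition fraction of one amino acid over the counted residues of a
#' sequence. Unknown residues (`X`) are excluded from the denominator, so
#' fractions over the 20 standard residues always sum to one.
#'
#' @param seq Amino-acid sequence (single string; case-insensitive;
#'   standard 20 letters plus `X`).
#' @param residue Single standard amino-acid letter to count.
#' @return Fraction in `[0, 1]`.
#' @examples
#' residue_fraction("GGGG", "G")   # 1
#' residue_fraction("GC", "C")     # 0.5
#' @export
residue_fraction <- function(seq, residue) {
  chars <- .aa_chars(seq)
  residue <- toupper(residue)
  if (!residue %in% AA_STANDARD) stop("residue must be one of the 20 standard letters")
  counted <- chars[chars != "X"]
  if (!length(counted)) {
    stop("degenerate sequence: no counted residues after removing 'X'")
  }
  sum(counted == residue) / length(counted)
}

#' Average molecular weight of a protein
#'
#' Sum of average-isotopic residue masses plus one water. `X` residues
#' contribute the mean residue mass (111.1 Da).
#'
#' @inheritParams residue_fraction
#' @return Mass in Daltons.
#' @examples
#' molecular_weight("G")  # glycine residue + water, about 75.07 Da
#' @export
molecular_weight <- function(seq) {
  chars <- .aa_chars(seq)
  sum(AA_RESIDUE_MASS[chars]) + MASS_WATER
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge over the two termini and the ionisable
#' side chains (D, E, C, Y, H, K, R) with the package's declared pKa table.
#'
#' @inheritParams residue_fraction
#' @param pH pH value (may be a vector).
#' @param include_termini Count the free N- and C-terminus (default `TRUE`).
#' @return Net charge (same length as `pH`); strictly decreasing in pH.
#' @export
net_charge <- function(seq, pH, include_termini = TRUE) {
  chars <- .aa_chars(seq)
  counts <- c(table(factor(chars, levels = AA_ALPHABET)))
  groups <- counts[names(counts) %in% names(PKA_TABLE)]
  groups <- groups[groups > 0]
  if (include_termini) {
    groups <- c(groups, Nterm = 1L, Cterm = 1L)
  }
  vapply(pH, function(p) {
    z <- 0
    for (g in names(groups)) {
      pka <- PKA_TABLE[[g]]
      if (g %in% PKA_POSITIVE) {
        z <- z + groups[[g]] / (1 + 10^(p - pka))
      } else {
        z <- z - groups[[g]] / (1 + 10^(pka - p))
      }
    }
    z
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' pH at which the net charge is zero, found by bisection on `[0, 14]`.
#' Net charge is strictly decreasing in pH, so the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units (default `1e-4`).
#' @return pI in pH units. A peptide with no ionisable groups at all
#'   (possible only when `include_termini = FALSE`) returns the neutral
#'   convention value 7 with a warning and attribute `no_ionisable = TRUE`.
#' @examples
#' isoelectric_point("DDDD") < 4.5  # acidic peptide
#' isoelectric_point("KKKK") > 9    # basic peptide
#' @export
isoelectric_point <- function(seq, include_termini = TRUE, tol = 1e-4) {
  chars <- .aa_chars(seq)
  has_groups <- include_termini || any(chars %in% setdiff(names(PKA_TABLE), c("Nterm", "Cterm")))
  if (!has_groups) {
    warning("sequence has no ionisable groups; returning neutral pI = 7")
    return(structure(7, no_ionisable = TRUE))
  }
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, include_termini) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical property profile of a protein
#'
#' Bundles length, average molecular weight, pI and per-residue
#' composition fractions for one sequence.
#'
#' @inheritParams residue_fraction
#' @return An object of class `property_profile`: a list with elements
#'   `length` (counted residues, `X` excluded), `n_x` (number of `X`),
#'   `mol_weight` (Da), `pI`, and `fractions` (named vector over the 20
#'   standard residues, summing to 1).
#' @export
property_profile <- function(seq) {
  chars <- .aa_chars(seq)
  counted <- chars[chars != "X"]
  if (!length(counted)) stop("degenerate sequence: all residues are 'X'")
  fr <- c(table(factor(counted, levels = AA_STANDARD))) / length(counted)
  structure(
    list(
      length = length(counted),
      n_x = sum(chars == "X"),
      mol_weight = molecular_weight(seq),
      pI = as.numeric(isoelectric_point(seq)),
      fractions = fr
    ),
    class = "property_profile"
  )
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf("protein property profile: %d residues, MW %.1f Da, pI %.2f\n",
              x$length, x$mol_weight, x$pI))
  cat(sprintf("  Cys %.1f%%, Gly %.1f%%\n",
              100 * x$fractions[["C"]], 100 * x$fractions[["G"]]))
  invisible(x)
}

#' Construct a table of protein records
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Amino-acid sequences (standard 20 letters plus `X`).
#' @param source Free-text source tags (species/scaffold); recycled.
#' @return A `data.frame` with columns `id`, `sequence`, `source`.
#' @export
protein_records <- function(id, sequence, source = "") {
  if (anyDuplicated(id)) stop("protein ids must be unique")
  sequence <- vapply(sequence, .aa_check, character(1), USE.NAMES = FALSE)
  data.frame(id = as.character(id), sequence = sequence,
             source = rep_len(as.character(source), length(id)))
}

#' Read protein records from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; the
#' remainder of the header becomes the source tag.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A `data.frame` as from [protein_records()].
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  src <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_records(ids, as.character(aas), src)
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param path Output path.
#' @export
write_protein_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Tabulate physicochemical properties for a set of proteins
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @return A `data.frame` with one row per record: `id`, `length`,
#'   `mol_weight`, `pI`, `fraction_C`, `fraction_G`.
#' @export
property_table <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- property_profile(records$sequence[i])
    data.frame(id = records$id[i], length = p$length,
               mol_weight = p$mol_weight, pI = p$pI,
               fraction_C = p$fractions[["C"]],
               fraction_G = p$fractions[["G"]])
  })
  do.call(rbind, rows)
}
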