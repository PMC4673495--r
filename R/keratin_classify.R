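# Combinatorial classification of beta-keratins. Setae-associated
# corneous beta-proteins carry a conserved 20-residue core box and are
# cysteine-rich, small and basic; the classifier assigns each protein the
# subset of five diagnostic feature flags:
#   1  core-box similarity >= threshold (default 70% identity)
#   2  cysteine-rich        (Cys fraction > 0.10)
#   3  glycine-rich         (Gly fraction > 0.15)
#   4  basic                (pI > 7)
#   5  low molecular weight (MW < 15,000 Da)
# Flags 2-5 are strict inequalities; flag 1 is inclusive (>=).

#' Default setae core-box motif
#'
#' The conserved 20-residue core box diagnostic of setae beta-keratins.
#' @export
SETAE_CORE_BOX <- "SEVTIQPPPCTVVVPGPVLA"

#' Core-box similarity of a protein to a motif
#'
#' Maximum ungapped percent identity of the motif against all windows of
#' the sequence, with the motif length as denominator. When the sequence
#' is shorter than the motif the motif slides across the sequence and the
#' overhang counts as mismatch, so the score is bounded by
#' `100 * nchar(seq) / nchar(motif)`.
#'
#' A gapped alternative (`method = "local"`, Smith-Waterman via
#' [Biostrings::pairwiseAlignment()] with identities scored over the motif
#' length) is available but is not the default: the motif is short enough
#' that gaps are unnecessary at the 70% scale, and the ungapped scan is
#' fully deterministic.
#'
#' @param seq Amino-acid sequence (single string).
#' @param motif Motif string (default [SETAE_CORE_BOX]).
#' @param method `"ungapped"` (default) or `"local"`.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' corebox_similarity(SETAE_CORE_BOX)  # 100
#' @export
corebox_similarity <- function(seq, motif = SETAE_CORE_BOX,
                               method = c("ungapped", "local")) {
  method <- match.arg(method)
  s <- .aa_chars(seq)
  m <- .aa_chars(motif)
  L <- length(m)
  if (L < 5L) stop("motif must have at least 5 residues")
  n <- length(s)
  if (method == "local") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(s, collapse = "")),
      Biostrings::AAString(paste(m, collapse = "")),
      type = "local", substitutionMatrix = NULL,
      gapOpening = 10, gapExtension = 4
    )
    return(100 * Biostrings::nmatch(aln) / L)
  }
  if (n >= L) {
    offsets <- 0:(n - L)
    best <- max(vapply(offsets, function(o) sum(s[o + seq_len(L)] == m),
                       numeric(1)))
  } else {
    # motif longer than sequence: slide, overhang counted as mismatch
    offsets <- (1L - L):(n - 1L)
    best <- max(vapply(offsets, function(o) {
      j <- seq_len(L) + o          # sequence positions facing motif 1..L
      keep <- j >= 1L & j <= n
      sum(s[j[keep]] == m[keep])
    }, numeric(1)))
  }
  100 * best / L
}

#' Default thresholds for the beta-keratin feature flags
#'
#' @param min_identity Core-box percent identity for flag 1 (inclusive).
#' @param cys Cys fraction above which flag 2 is set (strict).
#' @param gly Gly fraction above which flag 3 is set (strict).
#' @param pi pI above which flag 4 is set (strict).
#' @param max_mw Molecular weight (Da) below which flag 5 is set (strict).
#' @return Named list of thresholds.
#' @export
keratin_thresholds <- function(min_identity = 70, cys = 0.10, gly = 0.15,
                               pi = 7, max_mw = 15000) {
  stopifnot(min_identity > 0, min_identity <= 100)
  list(min_identity = min_identity, cys = cys, gly = gly,
       pi = pi, max_mw = max_mw)
}

#' Classify one protein by the five beta-keratin feature flags
#'
#' @param id Record identifier.
#' @param seq Amino-acid sequence.
#' @param motif Core-box motif (default [SETAE_CORE_BOX]).
#' @param thresholds As from [keratin_thresholds()].
#' @param method Motif scan method, see [corebox_similarity()].
#' @return An object of class `keratin_profile`: list with `record_id`,
#'   `corebox_pct`, `flags` (sorted integer subset of 1:5), `label`
#'   (concatenated flags, or `"0"` when none) and the embedded
#'   `property_profile`.
#' @export
classify_keratin <- function(id, seq, motif = SETAE_CORE_BOX,
                             thresholds = keratin_thresholds(),
                             method = "ungapped") {
  prof <- property_profile(seq)
  pct <- corebox_similarity(seq, motif, method = method)
  flags <- integer(0)
  if (pct >= thresholds$min_identity)          flags <- c(flags, 1L)
  if (prof$fractions[["C"]] > thresholds$cys)  flags <- c(flags, 2L)
  if (prof$fractions[["G"]] > thresholds$gly)  flags <- c(flags, 3L)
  if (prof$pI > thresholds$pi)                 flags <- c(flags, 4L)
  if (prof$mol_weight < thresholds$max_mw)     flags <- c(flags, 5L)
  structure(
    list(record_id = id, corebox_pct = pct, flags = flags,
         label = if (length(flags)) paste(flags, collapse = "") else "0",
         property_profile = prof),
    class = "keratin_profile"
  )
}

#' @export
print.keratin_profile <- function(x, ...) {
  cat(sprintf("%s: core box %.1f%%, flags [%s]\n",
              x$record_id, x$corebox_pct, x$label))
  invisible(x)
}

#' Classify a table of protein records
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @inheritParams classify_keratin
#' @return A list of `keratin_profile` objects, one per record.
#' @export
classify_keratins <- function(records, motif = SETAE_CORE_BOX,
                              thresholds = keratin_thresholds(),
                              method = "ungapped") {
  lapply(seq_len(nrow(records)), function(i) {
    classify_keratin(records$id[i], records$sequence[i],
                     motif = motif, thresholds = thresholds, method = method)
  })
}

#' Flatten keratin profiles to a table
#'
#' @param profiles List of `keratin_profile` objects.
#' @return Data frame with columns `id`, `corebox_pct`, `flags`, `label`,
#'   `mw`, `pI`, `frac_C`, `frac_G`.
#' @export
keratin_profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(id = p$record_id, corebox_pct = p$corebox_pct,
               flags = paste(p$flags, collapse = ","), label = p$label,
               mw = p$property_profile$mol_weight,
               pI = p$property_profile$pI,
               frac_C = p$property_profile$fractions[["C"]],
               frac_G = p$property_profile$fractions[["G"]])
  }))
}

#' Summarise feature flags over a protein family
#'
#' Per-flag counts and a cross-tabulation of combination labels,
#' independent of the input order.
#'
#' @param profiles List of `keratin_profile` objects (may be empty).
#' @return List with `n` (profiles summarised), `flag_counts` (named
#'   vector over flags 1-5) and `label_counts` (named vector over observed
#'   combination labels, sorted).
#' @export
summarize_family <- function(profiles) {
  if (!length(profiles)) {
    return(list(n = 0L,
                flag_counts = setNames(integer(5), as.character(1:5)),
                label_counts = integer(0)))
  }
  flag_counts <- vapply(1:5, function(f) {
    sum(vapply(profiles, function(p) f %in% p$flags, logical(1)))
  }, integer(1))
  labels <- vapply(profiles, `[[`, character(1), "label")
  tab <- table(labels)
  list(n = length(profiles),
       flag_counts = setNames(flag_counts, as.character(1:5)),
       label_counts = setNames(as.integer(tab), names(tab))[order(names(tab))])
}
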