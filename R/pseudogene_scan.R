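# ORF/exon disruption scanning: the machinery used to call visual-opsin
# pseudogenes (rod RH1, cone SWS2) from lost initiation/termination
# codons, premature stops, frameshifts, and exons that are lost,
# incomplete or shifted relative to a functional ortholog.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.dna_check <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty nucleotide sequence")
  if (grepl("[^ACGTN]", seq)) stop("invalid nucleotide character in sequence")
  seq
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.codons <- function(seq) {
  n <- (nchar(seq) %/% 3L) * 3L
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Construct a gene model
#'
#' Exon coordinates are 0-based half-open genomic intervals, listed in
#' transcript (5' to 3') order: ascending for `+` strand genes, descending
#' for `-` strand genes.
#'
#' @param id Gene identifier.
#' @param exons Two-column matrix or data frame of `(start, end)`.
#' @param strand `"+"` or `"-"`.
#' @param contig Contig/scaffold identifier the coordinates refer to.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(id, exons, strand = "+", contig = "") {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  stopifnot(ncol(exons) == 2L, nrow(exons) >= 1L,
            all(exons[, "end"] > exons[, "start"]), all(exons[, "start"] >= 0L),
            strand %in% c("+", "-"))
  starts <- exons[, "start"]
  if (nrow(exons) > 1L) {
    ordered <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ordered) stop("exons must be listed in transcript orientation")
    gs <- sort(starts)
    ge <- sort(exons[, "end"])
    if (any(gs[-1L] < ge[-length(ge)])) stop("exons overlap")
  }
  if (sum(exons[, "end"] - exons[, "start"]) < 3L) stop("total CDS length < 3")
  structure(list(id = id, exons = exons, strand = strand, contig = contig),
            class = "gene_model")
}

#' Splice a coding sequence from a gene model
#'
#' Exons are extracted from the contig and concatenated in transcript
#' order; minus-strand exons are reverse-complemented.
#'
#' @param model A [gene_model()].
#' @param contig Nucleotide sequence of the contig (single string).
#' @return CDS nucleotide string.
#' @export
splice_cds <- function(model, contig) {
  contig <- .dna_check(contig)
  n <- nchar(contig)
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons[i, "start"]
    e <- model$exons[i, "end"]
    if (s < 0L || e > n) {
      stop(sprintf("exon %d of %s out of contig range [0, %d): %d-%d",
                   i, model$id, n, s, e))
    }
    x <- substr(contig, s + 1L, e)
    if (model$strand == "-") .revcomp(x) else x
  }, character(1))
  paste(pieces, collapse = "")
}

#' Scan an ORF for start/stop disruptions
#'
#' @param cds CDS nucleotide string (length >= 3). A length that is not a
#'   multiple of 3 is reported as a terminal frameshift and the truncated
#'   frame is scanned.
#' @return List with `lost_start` (first codon not ATG), `premature_stops`
#'   (1-based codon indices of stops strictly before the last codon),
#'   `lost_stop` (last codon not a stop) and `terminal_frameshift`.
#' @examples
#' scan_orf("ATGAAATAA")  # intact mini-ORF
#' @export
scan_orf <- function(cds) {
  cds <- .dna_check(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  codons <- .codons(cds)
  k <- length(codons)
  stops <- which(codons %in% STOP_CODONS)
  list(
    lost_start = codons[1L] != "ATG",
    premature_stops = as.integer(stops[stops < k]),
    lost_stop = !(codons[k] %in% STOP_CODONS),
    terminal_frameshift = (nchar(cds) %% 3L) != 0L
  )
}

# global alignment of two nucleotide strings; returns the two gapped
# aligned strings (pattern = candidate, subject = reference)
.align_pair <- function(cand, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cand), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 2
  )
  list(cand = as.character(Biostrings::alignedPattern(aln)),
       ref = as.character(Biostrings::alignedSubject(aln)))
}

# percent identity of candidate exon against a reference exon, with the
# reference exon length as denominator, plus reference coverage and the
# internal (non-terminal) gap runs of the alignment
.exon_alignment_stats <- function(cand, ref) {
  al <- .align_pair(cand, ref)
  a <- strsplit(al$cand, "", fixed = TRUE)[[1L]]
  b <- strsplit(al$ref, "", fixed = TRUE)[[1L]]
  both <- a != "-" & b != "-"
  matches <- sum(a == b & both)
  ref_len <- sum(b != "-")
  # internal indel runs: gap runs in either row not touching an alignment end
  r <- rle(paste0(ifelse(a == "-", "a", "."), ifelse(b == "-", "b", ".")))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  indels <- data.frame(ref_pos = integer(0), length = integer(0))
  refpos <- cumsum(b != "-")
  for (i in seq_along(r$values)) {
    if (r$values[i] == "..") next
    if (starts[i] == 1L || ends[i] == length(a)) next  # terminal gap: length difference, not internal indel
    indels <- rbind(indels, data.frame(
      ref_pos = refpos[starts[i]], length = r$lengths[i]))
  }
  list(identity = 100 * matches / nchar(ref),
       coverage = sum(both) / nchar(ref),
       indels = indels)
}

#' Compare a candidate gene model against a functional reference
#'
#' Exon-by-exon comparison of a candidate gene (model + contig) with a
#' functional ortholog. Candidate exons are paired with reference exons by
#' an order-preserving best-identity assignment (exon rearrangement is not
#' assumed); a reference exon with no eligible partner is reported
#' missing, a matched exon covering less than `coverage_floor` of the
#' reference is incomplete, internal indels of length not divisible by 3
#' are frameshifts, and exons whose cumulative coding offset is not a
#' multiple of 3 are shifted. ORF start/stop flags come from [scan_orf()]
#' on the spliced candidate, assessed relative to the reference (a defect
#' shared with the reference is not charged to the candidate).
#'
#' @param model Candidate [gene_model()].
#' @param contig Candidate contig sequence.
#' @param ref_cds Reference CDS nucleotide string (must translate without
#'   internal stops).
#' @param ref_exon_lengths Integer vector of reference exon lengths in bp,
#'   summing to `nchar(ref_cds)`.
#' @param identity_floor Percent identity below which a candidate exon
#'   does not count as present (default 50).
#' @param coverage_floor Reference-exon coverage below which a matched
#'   exon is reported incomplete (default 0.8).
#' @return Object of class `disruption_report` with fields `gene`,
#'   `lost_start`, `lost_stop`, `premature_stops`, `frameshifts` (data
#'   frame `exon`, `ref_pos`, `shift`), `missing_exons`, `incomplete_exons`,
#'   `shifted_exons` (data frame `exon`, `offset`), `terminal_frameshift`
#'   and `verdict` (`"functional"`, `"pseudogene"` or `"unresolvable"`).
#' @export
compare_to_functional <- function(model, contig, ref_cds, ref_exon_lengths,
                                  identity_floor = 50, coverage_floor = 0.8) {
  ref_cds <- .dna_check(ref_cds)
  stopifnot(sum(ref_exon_lengths) == nchar(ref_cds))
  ref_orf <- scan_orf(ref_cds)
  if (length(ref_orf$premature_stops)) {
    stop("reference CDS contains internal stop codons")
  }
  ends <- cumsum(ref_exon_lengths)
  starts <- ends - ref_exon_lengths + 1L
  ref_exons <- substring(ref_cds, starts, ends)
  contig <- .dna_check(contig)
  cand_exons <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons[i, "start"]
    e <- model$exons[i, "end"]
    if (s < 0L || e > nchar(contig)) {
      stop(sprintf("exon %d of %s out of contig range", i, model$id))
    }
    x <- substr(contig, s + 1L, e)
    if (model$strand == "-") .revcomp(x) else x
  }, character(1))

  R <- length(ref_exons)
  C <- length(cand_exons)
  stats <- vector("list", R * C)
  ident <- matrix(-Inf, R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      st <- .exon_alignment_stats(cand_exons[j], ref_exons[i])
      stats[[(i - 1L) * C + j]] <- st
      if (st$identity >= identity_floor) ident[i, j] <- st$identity
    }
  }

  # order-preserving assignment maximising total identity of matched pairs
  M <- matrix(0, R + 1L, C + 1L)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      pair <- if (is.finite(ident[i, j])) M[i, j] + ident[i, j] else -Inf
      M[i + 1L, j + 1L] <- max(M[i, j + 1L], M[i + 1L, j], pair)
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- R; j <- C
  while (i > 0L && j > 0L) {
    if (is.finite(ident[i, j]) &&
        isTRUE(all.equal(M[i + 1L, j + 1L], M[i, j] + ident[i, j]))) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }

  if (nrow(pairs) == 0L) {
    rep <- structure(list(
      gene = model$id, lost_start = NA, lost_stop = NA,
      premature_stops = integer(0),
      frameshifts = data.frame(exon = integer(0), ref_pos = integer(0),
                               shift = integer(0)),
      missing_exons = seq_len(R), incomplete_exons = integer(0),
      shifted_exons = data.frame(exon = integer(0), offset = integer(0)),
      terminal_frameshift = NA, verdict = "unresolvable"),
      class = "disruption_report")
    return(rep)
  }

  matched_ref <- pairs[, 1L]
  missing <- setdiff(seq_len(R), matched_ref)
  incomplete <- integer(0)
  frameshifts <- data.frame(exon = integer(0), ref_pos = integer(0),
                            shift = integer(0))
  cand_len_for_ref <- integer(R)  # candidate bp paired with each ref exon
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    st <- stats[[(i - 1L) * C + j]]
    cand_len_for_ref[i] <- nchar(cand_exons[j])
    if (st$coverage < coverage_floor) incomplete <- c(incomplete, i)
    if (nrow(st$indels)) {
      sh <- st$indels$length %% 3L
      keep <- sh != 0L
      if (any(keep)) {
        frameshifts <- rbind(frameshifts, data.frame(
          exon = i, ref_pos = st$indels$ref_pos[keep], shift = sh[keep]))
      }
    }
  }

  # cumulative coding offset entering each matched exon
  shifted <- data.frame(exon = integer(0), offset = integer(0))
  for (i in matched_ref) {
    before <- seq_len(R) < i
    offset <- sum(cand_len_for_ref[before]) - sum(ref_exon_lengths[before])
    if (offset %% 3L != 0L) {
      shifted <- rbind(shifted, data.frame(exon = i, offset = offset))
    }
  }

  cds <- splice_cds(model, contig)
  orf <- scan_orf(cds)
  lost_start <- orf$lost_start && !ref_orf$lost_start
  lost_stop <- orf$lost_stop && !ref_orf$lost_stop
  disrupted <- lost_start || lost_stop || length(orf$premature_stops) ||
    nrow(frameshifts) || length(missing) || length(incomplete) ||
    nrow(shifted) || orf$terminal_frameshift
  structure(list(
    gene = model$id,
    lost_start = lost_start,
    lost_stop = lost_stop,
    premature_stops = orf$premature_stops,
    frameshifts = frameshifts,
    missing_exons = missing,
    incomplete_exons = incomplete,
    shifted_exons = shifted,
    terminal_frameshift = orf$terminal_frameshift,
    verdict = if (disrupted) "pseudogene" else "functional"),
    class = "disruption_report")
}

#' @export
print.disruption_report <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$gene, x$verdict))
  if (isTRUE(x$lost_start)) cat("  initiation codon lost\n")
  if (isTRUE(x$lost_stop)) cat("  termination codon lost\n")
  if (length(x$premature_stops)) {
    cat("  premature stop(s) at codon", paste(x$premature_stops, collapse = ", "), "\n")
  }
  if (nrow(x$frameshifts)) cat(sprintf("  %d frameshift(s)\n", nrow(x$frameshifts)))
  if (length(x$missing_exons)) {
    cat("  missing exon(s):", paste(x$missing_exons, collapse = ", "), "\n")
  }
  if (length(x$incomplete_exons)) {
    cat("  incomplete exon(s):", paste(x$incomplete_exons, collapse = ", "), "\n")
  }
  if (nrow(x$shifted_exons)) {
    cat("  shifted exon(s):", paste(x$shifted_exons$exon, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten disruption reports to a table
#'
#' @param reports List of `disruption_report` objects.
#' @return Data frame with one row per gene.
#' @export
disruption_table <- function(reports) {
  do.call(rbind, lapply(reports, function(x) {
    data.frame(
      gene = x$gene, verdict = x$verdict,
      lost_start = isTRUE(x$lost_start), lost_stop = isTRUE(x$lost_stop),
      n_premature_stops = length(x$premature_stops),
      n_frameshifts = nrow(x$frameshifts),
      missing_exons = paste(x$missing_exons, collapse = ","),
      incomplete_exons = paste(x$incomplete_exons, collapse = ","),
      shifted_exons = paste(x$shifted_exons$exon, collapse = ","))
  }))
}
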