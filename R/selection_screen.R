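# Pairwise Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
# correction, codon-column alignment filtering (the role Gblocks plays in
# genome-scale screens), the positive-selection screen (Ka/Ks > 1), and
# the overlap of selected genes with post-autotomy expression upregulation.

# ---- codon machinery ------------------------------------------------------

.genetic_code <- function() Biostrings::GENETIC_CODE

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

# the nine single-nucleotide neighbours of a codon
.codon_neighbours <- function(codon) {
  nts <- c("A", "C", "G", "T")
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      x <- codon
      substr(x, pos, pos) <- nt
      out <- c(out, x)
    }
  }
  out
}

# fractional synonymous sites per sense codon (changes to stop codons are
# nonsynonymous), cached after first use
.ng86_site_table <- function() {
  if (!is.null(.geckoevo_cache$sites)) return(.geckoevo_cache$sites)
  gc <- .genetic_code()
  sense <- .sense_codons()
  s <- vapply(sense, function(cd) {
    nb <- .codon_neighbours(cd)
    sum(gc[nb] != "*" & gc[nb] == gc[[cd]]) / 3
  }, numeric(1))
  .geckoevo_cache$sites <- s
  s
}

# average synonymous/nonsynonymous differences between two sense codons:
# minimal mutational pathways weighted equally, pathways through stop
# codons excluded (if every pathway is blocked, all are used as fallback)
.ng86_pair_diffs <- function(c1, c2) {
  gc <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    if (nd == 2L) list(pos, rev(pos)) else {
      do.call(c, lapply(seq_len(3L), function(i) {
        rest <- pos[-i]
        list(c(pos[i], rest), c(pos[i], rev(rest)))
      }))
    }
  }
  eval_path <- function(order) {
    cur <- c1
    sd <- 0; ndf <- 0
    blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") blocked <- TRUE
      if (gc[[nxt]] != "*" && gc[[cur]] != "*" && gc[[nxt]] == gc[[cur]]) {
        sd <- sd + 1
      } else {
        ndf <- ndf + 1
      }
      cur <- nxt
    }
    list(sd = sd, nd = ndf, blocked = blocked)
  }
  paths <- lapply(perms, eval_path)
  valid <- paths[!vapply(paths, `[[`, logical(1), "blocked")]
  if (!length(valid)) valid <- paths
  c(sd = mean(vapply(valid, `[[`, numeric(1), "sd")),
    nd = mean(vapply(valid, `[[`, numeric(1), "nd")))
}

# cached 61x61 lookup of pairwise differences
.ng86_diff_tables <- function() {
  if (!is.null(.geckoevo_cache$diff_sd)) {
    return(list(sd = .geckoevo_cache$diff_sd, nd = .geckoevo_cache$diff_nd))
  }
  sense <- .sense_codons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  ndm <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- .ng86_pair_diffs(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- d[["sd"]]
      ndm[i, j] <- ndm[j, i] <- d[["nd"]]
    }
  }
  .geckoevo_cache$diff_sd <- sd
  .geckoevo_cache$diff_nd <- ndm
  list(sd = sd, nd = ndm)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' Fractional synonymous (`s`) and nonsynonymous (`n`) site counts of a
#' sense codon: for each of the nine single-nucleotide neighbours the
#' change is classified under the standard nuclear code, with changes to
#' stop codons counted as nonsynonymous; `s + n = 3` always.
#'
#' @param codon A sense codon (3-mer over ACGT).
#' @return Named numeric vector `c(s, n)`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3: only TTC is synonymous
#' ng86_sites("TGG")  # s = 0: tryptophan has a single codon
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be a 3-mer over ACGT")
  }
  if (.genetic_code()[[codon]] == "*") stop("stop codon has no NG86 sites")
  s <- .ng86_site_table()[[codon]]
  c(s = s, n = 3 - s)
}

#' Pairwise Nei-Gojobori Ka/Ks estimate
#'
#' NG86 counting over the shared ungapped codons of an in-frame pair:
#' sites averaged over the two sequences, multi-hit codons averaged over
#' all minimal mutational pathways with equal weights (pathways through
#' stop codons excluded), proportions Jukes-Cantor corrected
#' (`K = -3/4 ln(1 - 4p/3)`). Codons containing gaps, ambiguity characters
#' or stop codons are skipped.
#'
#' @param seq1,seq2 In-frame nucleotide sequences of equal length (gaps as
#'   `-`), or a length-2 character vector/list as `seq1`.
#' @return Object of class `kaks_result`: `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ka`, `Ks`, `ratio`, `flag` (`"ok"`, `"Ks_zero"` or
#'   `"saturated"`) and `codons` (codons compared).
#' @export
ng86_kaks <- function(seq1, seq2 = NULL) {
  if (is.null(seq2)) {
    stopifnot(length(seq1) == 2L)
    seq2 <- seq1[[2L]]
    seq1 <- seq1[[1L]]
  }
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)")
  if (nchar(seq1) %% 3L != 0L) stop("alignment length not divisible by 3")
  cd1 <- .codons(seq1)
  cd2 <- .codons(seq2)
  sense <- .sense_codons()
  ok <- cd1 %in% sense & cd2 %in% sense
  if (!any(ok)) stop("no shared ungapped sense codons")
  cd1 <- cd1[ok]; cd2 <- cd2[ok]
  st <- .ng86_site_table()
  S <- sum((st[cd1] + st[cd2]) / 2)
  N <- 3 * length(cd1) - S
  tabs <- .ng86_diff_tables()
  idx <- cbind(match(cd1, sense), match(cd2, sense))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  flag <- "ok"
  Ka <- Ks <- ratio <- NA_real_
  if (pS >= 3 / 4 || pN >= 3 / 4) {
    flag <- "saturated"
  } else {
    Ks <- jc(pS)
    Ka <- jc(pN)
    if (Ks == 0) {
      flag <- "Ks_zero"
    } else {
      ratio <- Ka / Ks
    }
  }
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ka = Ka, Ks = Ks, ratio = ratio,
                 flag = flag, codons = length(cd1)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka %.4f, Ks %.4f, Ka/Ks %s (%d codons, flag %s)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$codons, x$flag))
  invisible(x)
}

# ---- alignment filtering --------------------------------------------------

#' Filter ambiguous codon columns from an in-frame alignment
#'
#' Simplified codon-column filter in the role Gblocks plays upstream of a
#' Ka/Ks screen: a codon column is dropped when its gap fraction exceeds
#' `max_gap_fraction` or when the most common codon occurs in fewer than
#' `min_conserved_fraction` of the sequences; surviving runs shorter than
#' `min_block_codons` columns are then dropped too, so the output stays
#' frame-valid.
#'
#' @param alignment Named character vector of equal-length in-frame
#'   sequences (length divisible by 3; gaps as `-`).
#' @param min_conserved_fraction Minimum frequency of the modal codon
#'   (default 0.5).
#' @param max_gap_fraction Maximum fraction of sequences with a gap in the
#'   codon column (default 0.2).
#' @param min_block_codons Minimum surviving run length in codons
#'   (default 3).
#' @return Filtered alignment (same names). When everything is filtered
#'   the result has zero width and attribute `empty = TRUE`.
#' @export
filter_blocks <- function(alignment, min_conserved_fraction = 0.5,
                          max_gap_fraction = 0.2, min_block_codons = 3) {
  alignment <- toupper(alignment)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("sequences must be aligned (equal length)")
  if (w %% 3L != 0L) stop("alignment length not divisible by 3")
  ncod <- w %/% 3L
  nseq <- length(alignment)
  cods <- vapply(alignment, .codons, character(ncod))
  if (ncod == 1L) cods <- matrix(cods, nrow = 1L)
  keep <- vapply(seq_len(ncod), function(k) {
    col <- cods[k, ]
    gapped <- grepl("-", col, fixed = TRUE)
    if (sum(gapped) / nseq > max_gap_fraction) return(FALSE)
    solid <- col[!gapped]
    if (!length(solid)) return(FALSE)
    max(table(solid)) / nseq >= min_conserved_fraction
  }, logical(1))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] < min_block_codons) {
      keep[(ends[i] - r$lengths[i] + 1L):ends[i]] <- FALSE
    }
  }
  if (!any(keep)) {
    out <- setNames(rep("", nseq), names(alignment))
    attr(out, "empty") <- TRUE
    return(out)
  }
  idx <- which(keep)
  out <- vapply(seq_len(nseq), function(s) {
    paste(cods[idx, s], collapse = "")
  }, character(1))
  setNames(out, names(alignment))
}

# ---- PSG screen -----------------------------------------------------------

#' Screen ortholog alignments for positively selected genes
#'
#' For every gene the focal sequence is compared with each comparator by
#' [ng86_kaks()] (after optional [filter_blocks()]); the gene statistic is
#' the mean of the defined pairwise Ka/Ks ratios, and genes whose
#' statistic exceeds `threshold` are listed as candidates. Genes whose
#' pairs are all saturated/undefined, or with fewer compared codons than
#' `min_codons`, are excluded and logged.
#'
#' @param orthologs Named list of per-gene codon alignments (named
#'   character vectors including the focal sequence).
#' @param focal Name of the focal-species sequence within each alignment.
#' @param threshold Ka/Ks ratio above which a gene is a candidate
#'   (default 1, strict).
#' @param min_codons Minimum compared codons per pair (default 30).
#' @param filter Apply [filter_blocks()] first (default `TRUE`).
#' @param ... Passed to [filter_blocks()].
#' @return List with `psg` (candidate table: gene, codons, S, N, Sd, Nd,
#'   Ka, Ks, ratio, n_pairs), `all` (same columns for every scored gene)
#'   and `excluded` (gene, reason).
#' @export
screen_psg <- function(orthologs, focal, threshold = 1, min_codons = 30,
                       filter = TRUE, ...) {
  stopifnot(length(orthologs) >= 1L, !is.null(names(orthologs)))
  rows <- list()
  excluded <- data.frame(gene = character(0), reason = character(0))
  for (g in names(orthologs)) {
    aln <- orthologs[[g]]
    if (!focal %in% names(aln)) {
      excluded <- rbind(excluded, data.frame(gene = g, reason = "no_focal_sequence"))
      next
    }
    if (filter) {
      aln <- filter_blocks(aln, ...)
      if (isTRUE(attr(aln, "empty"))) {
        excluded <- rbind(excluded, data.frame(gene = g, reason = "filtered_empty"))
        next
      }
    }
    comps <- setdiff(names(aln), focal)
    res <- lapply(comps, function(cm) {
      tryCatch(ng86_kaks(aln[[focal]], aln[[cm]]), error = function(e) NULL)
    })
    res <- Filter(Negate(is.null), res)
    defined <- Filter(function(r) r$flag == "ok", res)
    if (!length(defined)) {
      excluded <- rbind(excluded, data.frame(gene = g, reason = "no_defined_ratio"))
      next
    }
    codons <- min(vapply(defined, `[[`, numeric(1), "codons"))
    if (codons < min_codons) {
      excluded <- rbind(excluded, data.frame(gene = g, reason = "too_few_codons"))
      next
    }
    mean_of <- function(f) mean(vapply(defined, `[[`, numeric(1), f))
    rows[[g]] <- data.frame(
      gene = g, codons = codons, n_pairs = length(defined),
      S = mean_of("S_sites"), N = mean_of("N_sites"),
      Sd = mean_of("Sd"), Nd = mean_of("Nd"),
      Ka = mean_of("Ka"), Ks = mean_of("Ks"), ratio = mean_of("ratio"))
  }
  all_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), codons = numeric(0), n_pairs = integer(0),
               S = numeric(0), N = numeric(0), Sd = numeric(0), Nd = numeric(0),
               Ka = numeric(0), Ks = numeric(0), ratio = numeric(0))
  rownames(all_tab) <- NULL
  psg <- all_tab[all_tab$ratio > threshold, , drop = FALSE]
  rownames(psg) <- NULL
  if (nrow(excluded)) {
    message(nrow(excluded), " gene(s) excluded from the screen")
  }
  list(psg = psg, all = all_tab, excluded = excluded)
}

# ---- expression overlap ---------------------------------------------------

#' Read a post-autotomy expression timecourse table
#'
#' Tab-separated with header columns `gene`, `d0`, `d1`, `d3`, `d7`
#' (expression at 0, 1, 3 and 7 days after tail autotomy).
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_expression_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "d0", "d1", "d3", "d7")
  if (!all(need %in% names(tab))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab[, c("d0", "d1", "d3", "d7")] < 0)) stop("negative expression values")
  tab
}

#' Fraction of selected genes upregulated after autotomy
#'
#' A gene counts as upregulated when its expression at any post-autotomy
#' timepoint (1, 3 or 7 days) is at least `fold_threshold` times its day-0
#' value. Genes with zero day-0 expression count as upregulated when any
#' later value is positive. Ids absent from the table are logged and
#' excluded from the denominator.
#'
#' @param psg_ids Character vector of gene ids (e.g. PSG candidates).
#' @param table Expression table as from [read_expression_table()].
#' @param fold_threshold Fold-change threshold (default 2; inclusive).
#' @return List with `numerator`, `denominator`, `fraction` (`NA` when the
#'   denominator is 0) and `missing` (ids not found).
#' @export
expression_overlap <- function(psg_ids, table, fold_threshold = 2) {
  stopifnot(fold_threshold > 0)
  missing <- setdiff(psg_ids, table$gene)
  if (length(missing)) {
    message(length(missing), " id(s) missing from the expression table")
  }
  ids <- intersect(psg_ids, table$gene)
  rows <- table[match(ids, table$gene), , drop = FALSE]
  up <- vapply(seq_len(nrow(rows)), function(i) {
    base <- rows$d0[i]
    later <- c(rows$d1[i], rows$d3[i], rows$d7[i])
    if (base == 0) any(later > 0) else any(later / base >= fold_threshold)
  }, logical(1))
  num <- sum(up)
  den <- length(ids)
  list(numerator = num, denominator = den,
       fraction = if (den > 0) num / den else NA_real_,
       missing = missing)
}
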