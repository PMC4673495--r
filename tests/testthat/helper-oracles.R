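# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# --- pI oracle: net charge evaluated directly on a 0.001-pH grid ----------
# (same declared pKa convention as the package, independent evaluation)
oracle_net_charge <- function(seq, pH) {
  pka_pos <- c(Nterm = 8.6, H = 6.5, K = 10.8, R = 12.5)
  pka_neg <- c(Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, Y = 10.1)
  chars <- strsplit(seq, "")[[1L]]
  cnt <- function(a) sum(chars == a)
  z <- 1 / (1 + 10^(pH - pka_pos[["Nterm"]])) -
       1 / (1 + 10^(pka_neg[["Cterm"]] - pH))
  for (a in c("H", "K", "R")) z <- z + cnt(a) / (1 + 10^(pH - pka_pos[[a]]))
  for (a in c("C", "D", "E", "Y")) z <- z - cnt(a) / (1 + 10^(pka_neg[[a]] - pH))
  z
}

oracle_pi_grid <- function(seq, step = 0.001) {
  grid <- seq(0, 14, by = step)
  z <- oracle_net_charge(seq, grid)
  grid[which.min(abs(z))]
}

# --- core-box scan oracle: naive double loop ------------------------------
oracle_corebox <- function(seq, motif) {
  s <- strsplit(seq, "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  L <- length(m)
  n <- length(s)
  offsets <- if (n >= L) 0:(n - L) else (1L - L):(n - 1L)
  best <- 0
  for (o in offsets) {
    hits <- 0
    for (k in 1:L) {
      j <- k + o
      if (j >= 1 && j <= n && s[j] == m[k]) hits <- hits + 1
    }
    best <- max(best, hits)
  }
  100 * best / L
}

# --- NG86 oracles: direct enumeration against the genetic code ------------
GC_STD <- Biostrings::GENETIC_CODE

oracle_ng86_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GC_STD[[mut]] != "*" && GC_STD[[mut]] == GC_STD[[codon]]) syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# average (sd, nd) between two sense codons: equal-weight minimal pathways,
# stop-traversing paths excluded (all paths if none survive)
oracle_ng86_pair <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  counts <- list()
  for (ord in perms_of(pos)) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC_STD[[nxt]] == "*") blocked <- TRUE
      if (!blocked && GC_STD[[nxt]] == GC_STD[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    counts[[length(counts) + 1L]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  ok <- Filter(function(x) !x$blocked, counts)
  if (!length(ok)) ok <- counts
  c(sd = mean(sapply(ok, `[[`, "sd")),
    nd = mean(sapply(ok, `[[`, "nd")))
}

random_sense_codon <- function() {
  sense <- names(GC_STD)[GC_STD != "*"]
  sample(sense, 1L)
}

# --- codon-column filter oracle -------------------------------------------
oracle_filter_blocks <- function(aln, min_cons, max_gap, min_block) {
  w <- nchar(aln[[1L]])
  ncod <- w %/% 3L
  codons <- function(x) substring(x, seq(1, w, 3), seq(3, w, 3))
  cods <- sapply(aln, codons)
  if (ncod == 1L) cods <- matrix(cods, nrow = 1L)
  keep <- logical(ncod)
  for (k in seq_len(ncod)) {
    col <- cods[k, ]
    gap <- grepl("-", col, fixed = TRUE)
    if (sum(gap) / length(col) > max_gap) next
    solid <- col[!gap]
    if (length(solid) && max(table(solid)) / length(col) >= min_cons) keep[k] <- TRUE
  }
  # drop kept runs shorter than min_block
  k <- 1L
  while (k <= ncod) {
    if (keep[k]) {
      j <- k
      while (j < ncod && keep[j + 1L]) j <- j + 1L
      if (j - k + 1L < min_block) keep[k:j] <- FALSE
      k <- j + 1L
    } else k <- k + 1L
  }
  sapply(aln, function(x) paste(codons(x)[keep], collapse = ""))
}
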