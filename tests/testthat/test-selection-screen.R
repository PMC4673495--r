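# NG86 site/difference counting, Ka/Ks estimation, block filtering,
# the PSG screen and the expression overlap statistic.

test_that("NG86 site counts match exhaustive neighbour enumeration", {
  expect_equal(ng86_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_sites("TGG"), c(s = 0, n = 3))
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("TTN"), "codon")
  set.seed(61)
  for (i in 1:60) {
    cd <- random_sense_codon()
    expect_equal(ng86_sites(cd), oracle_ng86_sites(cd))
    expect_equal(sum(ng86_sites(cd)), 3)
  }
})

test_that("pairwise difference counting matches the pathway oracle", {
  set.seed(62)
  for (i in 1:80) {
    c1 <- random_sense_codon()
    c2 <- random_sense_codon()
    r <- ng86_kaks(c1, c2)
    o <- oracle_ng86_pair(c1, c2)
    expect_equal(r$Sd, unname(o[["sd"]]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(o[["nd"]]), tolerance = 1e-12)
  }
})

test_that("Ka/Ks estimates behave on constructed pairs", {
  ident <- paste(rep("ATGAAA", 50), collapse = "")
  r0 <- ng86_kaks(ident, ident)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_equal(r0$flag, "Ks_zero")

  # one synonymous third-position change in 100 codons: Ka = 0, Ks > 0
  s1 <- paste(rep(c("TTT", "GGA"), 50), collapse = "")
  s2 <- sub("^TTT", "TTC", s1)
  r1 <- ng86_kaks(s1, s2)
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)
  expect_equal(r1$flag, "ok")

  # symmetry in the two sequences
  r2 <- ng86_kaks(s2, s1)
  expect_equal(r1$Ka, r2$Ka)
  expect_equal(r1$Ks, r2$Ks)
  expect_equal(r1$Sd, r2$Sd)
})

test_that("site counts conserve S + N = 3 x codons for random pairs", {
  set.seed(63)
  for (i in 1:25) {
    sim <- simulate_codon_pair(runif(1, 0.1, 3), kappa = 1, t = 0.2,
                               length = 60, seed = 6300 + i)
    r <- ng86_kaks(sim$alignment)
    expect_equal(r$S_sites + r$N_sites, 3 * r$codons, tolerance = 1e-9)
    expect_lte(r$Sd, r$S_sites)
    expect_lte(r$Nd, r$N_sites)
  }
})

test_that("block filtering matches a direct per-column evaluation", {
  ident <- c(a = "ATGAAATTTGGG", b = "ATGAAATTTGGG")
  expect_identical(filter_blocks(ident, min_block_codons = 1), ident)

  # a fully gapped codon column is removed at max_gap_fraction = 0
  gapped <- c(a = "ATG---TTTGGG", b = "ATGAAATTTGGG")
  out <- filter_blocks(gapped, max_gap_fraction = 0, min_block_codons = 1)
  expect_identical(unname(out), c("ATGTTTGGG", "ATGTTTGGG"))

  # random alignments: equality with the brute-force oracle
  set.seed(64)
  nts <- c("A", "C", "G", "T", "-")
  for (i in 1:25) {
    ncod <- sample(5:20, 1)
    aln <- sapply(1:4, function(s) {
      paste(sample(nts, ncod * 3, replace = TRUE, prob = c(rep(0.22, 4), 0.12)),
            collapse = "")
    })
    names(aln) <- paste0("s", 1:4)
    got <- filter_blocks(aln, 0.5, 0.2, 3)
    want <- oracle_filter_blocks(aln, 0.5, 0.2, 3)
    expect_identical(unname(unclass(got))[1:4], unname(want))
    # frame validity and no growth
    expect_true(all(nchar(got) %% 3 == 0))
    expect_lte(nchar(got[[1]]), nchar(aln[[1]]))
  }

  # everything filtered -> empty flag
  junk <- c(a = "ATGAAA", b = "CCCTTT")
  out <- filter_blocks(junk, min_conserved_fraction = 1, min_block_codons = 5)
  expect_true(isTRUE(attr(out, "empty")))
})

test_that("the PSG screen recovers planted selected genes", {
  sim <- simulate_ortholog_set(n_genes = 30, n_selected = 4,
                               omega_background = 0.2, omega_selected = 3,
                               t = 0.3, length = 300, seed = 65)
  res <- screen_psg(sim$orthologs, focal = "gecko", threshold = 1)
  expect_true(all(sim$selected %in% res$psg$gene))
  false_pos <- setdiff(res$psg$gene, sim$selected)
  expect_lte(length(false_pos), 1)
  # permutation invariance (modulo row order)
  res2 <- screen_psg(sim$orthologs[rev(names(sim$orthologs))],
                     focal = "gecko", threshold = 1)
  expect_setequal(res$psg$gene, res2$psg$gene)
  # infinite threshold empties the table
  res3 <- screen_psg(sim$orthologs, focal = "gecko", threshold = Inf)
  expect_equal(nrow(res3$psg), 0)
})

test_that("short and saturated genes are excluded with reasons", {
  short <- list(g1 = c(gecko = "ATGAAATTT", anolis = "ATGAAATTC"))
  expect_message(res <- screen_psg(short, "gecko", min_codons = 30,
                                   filter = FALSE),
                 "excluded")
  expect_equal(nrow(res$all) + nrow(res$excluded), 1)
  expect_equal(nrow(res$psg), 0)
})

test_that("expression overlap counts fold-change upregulation correctly", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    d0 = c(10, 10, 10, 0),
                    d1 = c(25, 10, 10, 0),
                    d3 = c(10, 21, 10, 0),
                    d7 = c(10, 10, 19, 0))
  ov <- expression_overlap(c("a", "b", "c", "d"), tab, fold_threshold = 2)
  expect_equal(ov$numerator, 2)  # a and b reach 2x; c peaks at 1.9x; d flat 0
  expect_equal(ov$denominator, 4)
  expect_equal(ov$fraction, 0.5)
  # fold threshold 1 counts any non-decrease
  ov1 <- expression_overlap(c("a", "b", "c"), tab, fold_threshold = 1)
  expect_equal(ov1$numerator, 3)
  # zero-baseline convention: counted up iff any later value positive
  tab$d1[4] <- 5
  expect_equal(expression_overlap("d", tab)$numerator, 1)
  # missing ids excluded from the denominator
  expect_message(ov2 <- expression_overlap(c("a", "zzz"), tab), "missing")
  expect_equal(ov2$denominator, 1)
  expect_equal(ov2$missing, "zzz")
})

test_that("planted expression fixtures return the exact planted fraction", {
  sim <- simulate_expression(100, planted_up_ids = 69, fold = 2,
                             noise_cv = 0, seed = 66)
  ov <- expression_overlap(sim$table$gene, sim$table, fold_threshold = 2)
  expect_equal(ov$fraction, 0.69)
  none <- simulate_expression(50, planted_up_ids = character(0), fold = 2,
                              noise_cv = 0, seed = 67)
  expect_equal(expression_overlap(none$table$gene, none$table)$numerator, 0)
})
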