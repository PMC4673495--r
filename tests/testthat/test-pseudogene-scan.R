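# CDS splicing, ORF scanning and candidate-vs-functional comparison.

test_that("splice_cds concatenates exons in transcript orientation", {
  m1 <- gene_model("g", matrix(c(0L, 6L), 1), "+", "c")
  expect_equal(splice_cds(m1, "ATGTAA"), "ATGTAA")
  m1m <- gene_model("g", matrix(c(0L, 6L), 1), "-", "c")
  expect_equal(splice_cds(m1m, "ATGTAA"), "TTACAT")
  m2 <- gene_model("g", matrix(c(0L, 3L, 6L, 9L), 2, byrow = TRUE), "+", "c")
  expect_equal(splice_cds(m2, "ATGCCCTAA"), "ATGTAA")
  expect_error(splice_cds(m1, "ATG"), "out of contig range")
})

test_that("splicing a mirrored minus-strand model recovers the same CDS", {
  gene <- simulate_gene(n_exons = 3, seed = 51)
  cds <- splice_cds(gene$model, gene$contig)
  n <- nchar(gene$contig)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene$contig)))
  mirrored <- gene$model$exons
  mirrored <- cbind(start = n - mirrored[, "end"], end = n - mirrored[, "start"])
  mm <- gene_model("g", mirrored, "-", "c")
  expect_equal(splice_cds(mm, rc), cds)
})

test_that("ORF scanning flags start, stop and frame defects", {
  intact <- scan_orf("ATGAAATAA")
  expect_false(intact$lost_start)
  expect_false(intact$lost_stop)
  expect_length(intact$premature_stops, 0)
  expect_false(intact$terminal_frameshift)
  expect_true(scan_orf("ATAAAATAA")$lost_start)
  expect_true(scan_orf("ATGAAAAAA")$lost_stop)
  # stop in the second codon (premature, 1-based codon index)
  expect_equal(scan_orf("ATGTAATAA")$premature_stops, 2L)
  expect_true(scan_orf("ATGAAATAAC")$terminal_frameshift)
})

test_that("identity comparison is sound: a gene matches itself cleanly", {
  for (seed in c(52, 53)) {
    gene <- simulate_gene(n_exons = 4, seed = seed)
    rep <- compare_to_functional(gene$model, gene$contig,
                                 gene$cds, gene$exon_lengths)
    expect_equal(rep$verdict, "functional")
    expect_false(rep$lost_start)
    expect_false(rep$lost_stop)
    expect_length(rep$premature_stops, 0)
    expect_equal(nrow(rep$frameshifts), 0)
    expect_length(rep$missing_exons, 0)
    expect_length(rep$incomplete_exons, 0)
    expect_equal(nrow(rep$shifted_exons), 0)
  }
})

test_that("each injected disruption class is detected", {
  gene <- simulate_gene(n_exons = 3, exon_length = 120, seed = 54)

  start_lost <- inject_disruptions(gene$model, gene$contig,
                                   list(list(type = "start_loss")))
  r <- compare_to_functional(start_lost$model, start_lost$contig,
                             gene$cds, gene$exon_lengths)
  expect_true(r$lost_start)
  expect_equal(r$verdict, "pseudogene")

  stop_lost <- inject_disruptions(gene$model, gene$contig,
                                  list(list(type = "stop_loss")))
  r <- compare_to_functional(stop_lost$model, stop_lost$contig,
                             gene$cds, gene$exon_lengths)
  expect_true(r$lost_stop)

  lost_exon <- inject_disruptions(gene$model, gene$contig,
                                  list(list(type = "delete_exon", exon = 2L)))
  r <- compare_to_functional(lost_exon$model, lost_exon$contig,
                             gene$cds, gene$exon_lengths)
  expect_true(2L %in% r$missing_exons)
  expect_equal(r$verdict, "pseudogene")

  fs <- inject_disruptions(gene$model, gene$contig,
                           list(list(type = "frameshift", pos = 60L)))
  r <- compare_to_functional(fs$model, fs$contig, gene$cds, gene$exon_lengths)
  expect_true(nrow(r$frameshifts) > 0 || nrow(r$shifted_exons) > 0)
  expect_equal(r$verdict, "pseudogene")

  shifted <- inject_disruptions(gene$model, gene$contig,
                                list(list(type = "shift_exon", exon = 2L,
                                          by = 4L)))
  r <- compare_to_functional(shifted$model, shifted$contig,
                             gene$cds, gene$exon_lengths)
  expect_true(nrow(r$shifted_exons) > 0 || nrow(r$frameshifts) > 0 ||
                length(r$incomplete_exons) > 0)
  expect_equal(r$verdict, "pseudogene")
})

test_that("frameshifts create downstream premature stops at the expected rate", {
  # a 1-bp insertion scrambles the downstream frame; over many replicates
  # the chance of at least one new stop is about 1 - (61/64)^k
  set.seed(55)
  hits <- 0L
  n_rep <- 120L
  ks <- integer(0)
  for (i in seq_len(n_rep)) {
    gene <- simulate_gene(n_exons = 1, exon_length = 150, flank = 10,
                          seed = 1000L + i)
    pos <- 30L
    fs <- inject_disruptions(gene$model, gene$contig,
                             list(list(type = "frameshift", pos = pos)))
    orf <- scan_orf(splice_cds(fs$model, fs$contig))
    ks <- c(ks, (nchar(gene$cds) - pos) %/% 3L)
    if (length(orf$premature_stops) > 0) hits <- hits + 1L
  }
  k <- mean(ks)
  expected <- 1 - (61 / 64)^k
  expect_gt(hits / n_rep, expected - 0.15)
})

test_that("an unalignable candidate is flagged unresolvable", {
  gene <- simulate_gene(n_exons = 2, seed = 56)
  junk <- simulate_gene(n_exons = 2, seed = 57)
  r <- compare_to_functional(junk$model, junk$contig,
                             gene$cds, gene$exon_lengths,
                             identity_floor = 90)
  expect_equal(r$verdict, "unresolvable")
  expect_equal(r$missing_exons, seq_along(gene$exon_lengths))
})

test_that("disruption injection is deterministic and conflict-checked", {
  gene <- simulate_gene(n_exons = 2, seed = 58)
  a <- inject_disruptions(gene$model, gene$contig,
                          list(list(type = "start_loss")))
  b <- inject_disruptions(gene$model, gene$contig,
                          list(list(type = "start_loss")))
  expect_identical(a$contig, b$contig)
  expect_error(inject_disruptions(gene$model, gene$contig,
                                  list(list(type = "start_loss"),
                                       list(type = "start_loss"))),
               "conflicting")
})
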