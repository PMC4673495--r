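# Distance matrices, neighbor joining, reference placement, clock fitting
# and expansion-burst dating.

test_that("p-distance and Poisson correction match direct counts", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAATT", c = "AAAAAAAAAA")
  d <- pairwise_distance(seqs, model = "p")
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  dp <- pairwise_distance(seqs, model = "poisson")
  expect_equal(dp["a", "b"], -log(0.8), tolerance = 1e-4)
  # gap columns deleted pairwise
  g <- c(a = "AA--AAAAAA", b = "AATTAAAAAA")
  expect_equal(pairwise_distance(g)["a", "b"], 0)
  # saturation flagged
  expect_error(pairwise_distance(c(a = "AAAA", b = "TTTT"), "poisson"),
               "saturated")
})

test_that("NJ inverts additive matrices exactly", {
  # 3-taxon closed form: d(AB)=2, d(AC)=4, d(BC)=4 -> a=1, b=1, c=3
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3, rooting = "none")
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)

  # random additive 5-taxon matrices: topology and path lengths recovered
  set.seed(31)
  for (i in 1:10) {
    true <- ape::rtree(5)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    dmat <- ape::cophenetic.phylo(true)
    rec <- neighbor_joining(dmat[true$tip.label, true$tip.label],
                            rooting = "none")
    drec <- ape::cophenetic.phylo(rec)[true$tip.label, true$tip.label]
    expect_lt(max(abs(drec - dmat)), 1e-9)
    expect_equal(phangorn::RF.dist(ape::unroot(true), rec), 0)
  }
})

test_that("midpoint rooting recovers the true root of ultrametric matrices", {
  bt <- simulate_burst_tree(c(80, 50, 30, 20), seed = 32)
  d <- ape::cophenetic.phylo(bt)
  rec <- neighbor_joining(d)
  expect_true(ape::is.ultrametric(rec, tol = 1e-8))
  expect_equal(phangorn::RF.dist(bt, rec, rooted = TRUE), 0)
})

test_that("reference placement labels by nearest subgroup with margin", {
  refs <- c(r1 = "AAAAAAAAAA", r2 = "AAAAAAAATT", r3 = "TTTTTTTTTT",
            r4 = "TTTTTTTTAA")
  labels <- c("alpha", "alpha", "gamma", "gamma")
  hit <- classify_by_placement("AAAAAAAAAA", refs, labels)
  expect_equal(hit$label, "alpha")
  expect_equal(hit$nearest, "r1")
  expect_gt(hit$support, 0)
  # identical to a gamma reference
  expect_equal(classify_by_placement("TTTTTTTTTT", refs, labels)$label, "gamma")
  # constructed equidistance between subgroups -> ambiguous
  tie <- classify_by_placement("AAAAATTTTT", refs[c("r1", "r3")],
                               c("alpha", "gamma"))
  expect_equal(tie$label, "ambiguous")
})

test_that("simulated queries return to their source subgroup", {
  fam <- simulate_family(lambda = 0.03, mu = 0, time = 60, rate = 0.002,
                         motif_conservation = 1, seed = 33)
  refs <- setNames(fam$records$sequence, fam$records$id)
  other <- random_proteins(4, length = nchar(refs[[1]]), seed = 34)
  refs_all <- c(refs, setNames(other$sequence, other$id))
  labels <- c(rep("alpha", length(refs)), rep("gamma", nrow(other)))
  # a lightly mutated copy of an alpha reference places as alpha
  q <- refs[[1]]
  substr(q, 3, 3) <- "W"
  res <- classify_by_placement(q, refs_all, labels)
  expect_equal(res$label, "alpha")
  expect_gt(res$support, 0)
})

test_that("clock rate is recovered exactly on clock-like trees", {
  rate <- 0.004
  bt <- simulate_burst_tree(c(156, 100, 98, 60, 58), seed = 35)
  tr <- scale_tree_branches(bt, rate)
  root_tips <- tr$tip.label  # MRCA of everything = root at 156 Myr
  fit1 <- fit_rate(tr, list(calibration_point(root_tips, 156)))
  expect_equal(fit1$rate, rate, tolerance = 1e-9)
  # single calibration: depth 0.5 at age 100 -> rate 0.005
  bt2 <- simulate_burst_tree(100, seed = 36)
  tr2 <- scale_tree_branches(bt2, 0.005)
  fit2 <- fit_rate(tr2, list(calibration_point(tr2$tip.label, 100)))
  expect_equal(fit2$rate, 0.005, tolerance = 1e-12)
  # two perfectly clock-like calibrations: zero residual
  cal2 <- list(calibration_point(root_tips, 156),
               calibration_point(root_tips, c(100, 212)))  # midpoint 156
  fit3 <- fit_rate(tr, cal2)
  expect_equal(fit3$rate, rate, tolerance = 1e-9)
  expect_lt(max(abs(fit3$points$residual)), 1e-12)
})

test_that("dating is scale-equivariant and errors on degenerate calibrations", {
  bt <- simulate_burst_tree(c(100, 99, 85, 84), seed = 37)
  tr <- scale_tree_branches(bt, 0.003)
  rep1 <- date_expansions(tr, 0.003, bt$tip.label, max_gap = 5)
  tr_scaled <- scale_tree_branches(tr, 7)
  rep2 <- date_expansions(tr_scaled, 0.021, bt$tip.label, max_gap = 5)
  expect_equal(rep1$ages$age, rep2$ages$age, tolerance = 1e-9)
  expect_error(calibration_point(bt$tip.label, 0))
})

test_that("burst segmentation follows the max-gap contract", {
  ages <- c(100, 98, 97, 85, 83)
  bt <- simulate_burst_tree(ages, seed = 38)
  tr <- scale_tree_branches(bt, 0.01)
  rep5 <- date_expansions(tr, 0.01, bt$tip.label, max_gap = 5)
  expect_equal(nrow(rep5$bursts), 2)
  expect_equal(rep5$bursts$start, c(100, 85), tolerance = 1e-9)
  expect_equal(rep5$bursts$end, c(97, 83), tolerance = 1e-9)
  expect_equal(rep5$bursts$n, c(3, 2))
  rep20 <- date_expansions(tr, 0.01, bt$tip.label, max_gap = 20)
  expect_equal(nrow(rep20$bursts), 1)
  expect_equal(c(rep20$bursts$start, rep20$bursts$end), c(100, 83),
               tolerance = 1e-9)
  # ages partition into bursts + singletons, independent of leaf order
  total <- sum(rep5$bursts$n) + length(rep5$singletons)
  expect_equal(total, nrow(rep5$ages))
  repv <- date_expansions(tr, 0.01, rev(bt$tip.label), max_gap = 5)
  expect_equal(repv$ages$age, rep5$ages$age)
  # degenerate clade
  expect_equal(nrow(date_expansions(tr, 0.01, bt$tip.label[1], 5)$ages), 0)
})

test_that("calibration config files parse point and interval ages", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# calibrations", "[calibration]",
               "mrca = [t1, t2]", "age = 156",
               "[calibration]", "mrca = [t3, t4]", "age = [51, 66]"), path)
  cals <- read_calibrations(path)
  expect_length(cals, 2)
  expect_equal(cals[[1]]$age, 156)
  expect_equal(cals[[2]]$age, 58.5)  # midpoint of 51-66
  expect_equal(read_calibrations(path, use = "hi")[[2]]$age, 66)
})
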