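# Distance trees, reference placement and strict-clock dating of
# gene-family expansion bursts. Tree inference at desk scale is
# distance-based (p-distance / Poisson correction + neighbor joining);
# dating assumes a single linear rate anchored by fossil calibration
# points, e.g. the divergence of avian scale and claw beta-keratins
# (~156 Myr ago) and the feather-keratin expansion (66-51 Myr ago).

#' Pairwise distances between aligned amino-acid sequences
#'
#' p-distance (mismatches over pairwise-compared sites, gap columns
#' deleted per pair) or its Poisson correction `-ln(1 - p)`.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @param model `"p"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(seqs, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be aligned (equal length)")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0L) stop("no compared sites between ", names(seqs)[i],
                         " and ", names(seqs)[j])
      p <- sum(mat[i, ok] != mat[j, ok]) / nc
      if (model == "poisson") {
        if (p >= 1) stop("saturated pair (p >= 1): ", names(seqs)[i], " vs ",
                         names(seqs)[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch lengths
#' are clamped to zero with a warning, then the tree is rooted.
#'
#' @param dist Symmetric distance matrix (or `dist` object) over >= 3 taxa.
#' @param rooting `"midpoint"` (default), `"outgroup"` or `"none"`.
#' @param outgroup Tip label(s), required when `rooting = "outgroup"`.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(dist, rooting = c("midpoint", "outgroup", "none"),
                             outgroup = NULL) {
  rooting <- match.arg(rooting)
  tr <- ape::nj(stats::as.dist(dist))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  switch(rooting,
    none = tr,
    midpoint = phangorn::midpoint(tr),
    outgroup = ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  )
}

#' Assign a query sequence to a labelled subgroup by nearest reference
#'
#' Used for olfactory-receptor Class I/II subgroups (alpha, beta, gamma,
#' delta, epsilon, zeta) and for opsin paralog assignment (RH1, RH2, SWS1,
#' SWS2, LWS). The query takes the subgroup label of its nearest reference
#' under the chosen distance; support is the margin between the best and
#' second-best subgroup mean distances. A tie between nearest references
#' of different subgroups yields the label `"ambiguous"`.
#'
#' @param query Query sequence, either pre-aligned to the reference
#'   alignment (same width) or unaligned (it is then pairwise-aligned to
#'   each reference with [Biostrings::pairwiseAlignment()]).
#' @param references Named character vector of aligned reference sequences.
#' @param labels Character vector of subgroup labels, one per reference.
#' @param model Distance model, see [pairwise_distance()].
#' @param seq_type `"AA"` or `"DNA"`, used only for unaligned queries.
#' @return List with `label`, `support` (margin, `NA` when only one
#'   subgroup is present), `nearest` (reference id) and `subgroup_means`.
#' @export
classify_by_placement <- function(query, references, labels,
                                  model = "p", seq_type = c("AA", "DNA")) {
  seq_type <- match.arg(seq_type)
  stopifnot(length(references) >= 1L, length(labels) == length(references))
  if (is.null(names(references))) names(references) <- paste0("ref", seq_along(references))
  width <- unique(nchar(references))
  if (length(width) != 1L) stop("reference sequences must be aligned")
  if (nchar(query) == width) {
    d <- vapply(references, function(r) {
      pairwise_distance(c(q = query, r = r), model = model)[1, 2]
    }, numeric(1))
  } else {
    d <- vapply(references, function(r) {
      ungapped <- gsub("-", "", r, fixed = TRUE)
      xs <- if (seq_type == "AA") Biostrings::AAString else Biostrings::DNAString
      aln <- Biostrings::pairwiseAlignment(xs(query), xs(ungapped), type = "global")
      1 - Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    }, numeric(1))
  }
  best <- which(d == min(d))
  best_labels <- unique(labels[best])
  subgroup_means <- vapply(split(d, labels), mean, numeric(1))
  means_sorted <- sort(subgroup_means)
  support <- if (length(means_sorted) > 1L) means_sorted[[2]] - means_sorted[[1]] else NA_real_
  label <- if (length(best_labels) > 1L) "ambiguous" else best_labels
  list(label = label, support = support,
       nearest = names(references)[best[1L]],
       distances = d, subgroup_means = subgroup_means)
}

#' Define a calibration point
#'
#' A named-node age constraint: the most recent common ancestor of a leaf
#' set has a known (fossil-derived) age, either a point value or an
#' interval in Myr.
#'
#' @param mrca_of Character vector of >= 2 leaf names.
#' @param age Single age in Myr, or length-2 interval `c(lo, hi)`.
#' @param use For interval ages: `"midpoint"` (default), `"lo"` or `"hi"`.
#' @return Object of class `calibration_point`.
#' @export
calibration_point <- function(mrca_of, age, use = c("midpoint", "lo", "hi")) {
  use <- match.arg(use)
  stopifnot(length(mrca_of) >= 2L, length(age) %in% 1:2, all(age > 0))
  if (length(age) == 2L) {
    age <- sort(age)
    point <- switch(use, midpoint = mean(age), lo = age[1], hi = age[2])
  } else {
    point <- age
  }
  structure(list(mrca_of = mrca_of, age_range = age, age = point),
            class = "calibration_point")
}

#' Mean root-to-tip depth of a node within its own subtree
#'
#' Mean path length (in the tree's branch-length units) from an internal
#' node to its descendant tips; the strict-clock estimate of the node's
#' depth in substitutions/site.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param node Internal node number (ape numbering). Default: all internal
#'   nodes.
#' @return Named numeric vector of depths.
#' @export
node_depth_subtree <- function(tree, node = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(node)) node <- (ntip + 1L):(ntip + tree$Nnode)
  depth_from_root <- ape::node.depth.edgelength(tree)
  vapply(node, function(nd) {
    tips <- if (nd <= ntip) nd else
      unlist(phangorn::Descendants(tree, nd, type = "tips"))
    mean(depth_from_root[tips]) - depth_from_root[nd]
  }, numeric(1)) |> setNames(as.character(node))
}

#' Fit a strict-clock substitution rate from calibration points
#'
#' For every calibration the MRCA of its leaf set is resolved and its
#' subtree depth (mean node-to-tip path length, substitutions/site)
#' computed; the rate is the least-squares slope through the origin of
#' depth versus age. Interval calibrations contribute their configured
#' point (midpoint by default).
#'
#' @param tree Rooted [ape::phylo] tree, branch lengths in
#'   substitutions/site.
#' @param calibrations List of [calibration_point()] objects (>= 1).
#' @return List of class `clock_fit`: `rate` (subst/site/Myr), and a
#'   per-calibration data frame `points` (node, depth, age, fitted_depth,
#'   residual).
#' @export
fit_rate <- function(tree, calibrations) {
  if (inherits(calibrations, "calibration_point")) calibrations <- list(calibrations)
  if (!length(calibrations)) stop("at least one calibration point is required")
  pts <- do.call(rbind, lapply(calibrations, function(cal) {
    missing <- setdiff(cal$mrca_of, tree$tip.label)
    if (length(missing)) stop("calibration leaves not in tree: ",
                              paste(missing, collapse = ", "))
    node <- ape::getMRCA(tree, cal$mrca_of)
    depth <- node_depth_subtree(tree, node)
    if (cal$age <= 0) stop("zero-age calibration")
    if (depth <= 0) stop("zero-depth calibration node")
    data.frame(node = node, depth = as.numeric(depth), age = cal$age)
  }))
  rate <- sum(pts$depth * pts$age) / sum(pts$age^2)
  pts$fitted_depth <- rate * pts$age
  pts$residual <- pts$depth - pts$fitted_depth
  structure(list(rate = rate, points = pts), class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("strict-clock rate: %.6g subst/site/Myr over %d calibration(s)\n",
              x$rate, nrow(x$points)))
  invisible(x)
}

#' Date duplication nodes of a clade and detect expansion bursts
#'
#' Every internal node of the clade spanned by `clade_leaves` is dated as
#' subtree depth / rate. Ages sorted in descending order are segmented
#' into maximal runs whose consecutive gaps are at most `max_gap`; runs of
#' two or more nodes are reported as bursts `[oldest, youngest]`, isolated
#' ages as singletons.
#'
#' @param tree Rooted [ape::phylo], branch lengths in substitutions/site.
#' @param rate Substitution rate in subst/site/Myr (> 0), e.g. from
#'   [fit_rate()].
#' @param clade_leaves Leaf names spanning the clade of interest.
#' @param max_gap Maximum within-burst age gap in Myr (default 5).
#' @return Object of class `expansion_report`: `ages` (data frame of node
#'   and age, descending), `bursts` (data frame `start`, `end`, `n`; start
#'   is the older bound) and `singletons` (numeric ages).
#' @export
date_expansions <- function(tree, rate, clade_leaves, max_gap = 5) {
  stopifnot(rate > 0, max_gap >= 0)
  clade_leaves <- intersect(clade_leaves, tree$tip.label)
  empty <- structure(list(
    ages = data.frame(node = integer(0), age = numeric(0)),
    bursts = data.frame(start = numeric(0), end = numeric(0), n = integer(0)),
    singletons = numeric(0)), class = "expansion_report")
  if (length(clade_leaves) < 2L) return(empty)
  root <- ape::getMRCA(tree, clade_leaves)
  nodes <- c(root, setdiff(unlist(phangorn::Descendants(tree, root, type = "all")),
                           seq_along(tree$tip.label)))
  ages <- node_depth_subtree(tree, nodes) / rate
  ord <- order(ages, decreasing = TRUE)
  ages_df <- data.frame(node = nodes[ord], age = as.numeric(ages[ord]))
  a <- ages_df$age
  run_id <- cumsum(c(1, diff(a) < -max_gap))
  bursts <- data.frame(start = numeric(0), end = numeric(0), n = integer(0))
  singles <- numeric(0)
  for (g in split(a, run_id)) {
    if (length(g) >= 2L) {
      bursts <- rbind(bursts, data.frame(start = max(g), end = min(g),
                                         n = length(g)))
    } else {
      singles <- c(singles, g)
    }
  }
  structure(list(ages = ages_df, bursts = bursts, singletons = singles),
            class = "expansion_report")
}

#' @export
print.expansion_report <- function(x, ...) {
  cat(sprintf("expansion report: %d dated nodes, %d burst(s), %d singleton(s)\n",
              nrow(x$ages), nrow(x$bursts), length(x$singletons)))
  if (nrow(x$bursts)) {
    for (i in seq_len(nrow(x$bursts))) {
      cat(sprintf("  burst %d: %.1f-%.1f Myr ago (%d nodes)\n",
                  i, x$bursts$start[i], x$bursts$end[i], x$bursts$n[i]))
    }
  }
  invisible(x)
}

#' Read calibration points from a config file
#'
#' Flat key-value format, one block per calibration:
#' ```
#' [calibration]
#' mrca = [leafA, leafB]
#' age = 156
#' ```
#' Interval ages are written `age = [51, 66]`.
#'
#' @param path Config file path.
#' @param use Interval handling, see [calibration_point()].
#' @return List of `calibration_point` objects.
#' @export
read_calibrations <- function(path, use = "midpoint") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- split(lines, cumsum(lines == "[calibration]"))
  blocks <- blocks[names(blocks) != "0"]
  lapply(blocks, function(bl) {
    bl <- bl[bl != "[calibration]"]
    kv <- .parse_kv(bl)
    if (is.null(kv$mrca) || is.null(kv$age)) {
      stop("calibration block needs 'mrca' and 'age'")
    }
    calibration_point(kv$mrca, as.numeric(kv$age), use = use)
  })
}

# parse `key = value` lines; [a, b] becomes a vector
.parse_kv <- function(lines) {
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "[")) {
      val <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1L]])
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
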