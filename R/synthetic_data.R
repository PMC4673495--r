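# Generators for every input the pipeline consumes, each with planted,
# machine-readable ground truth: gene families by birth-death duplication
# with a conserved core-box motif, omega-controlled codon pair alignments,
# gene models with injected ORF/exon disruptions, and post-autotomy
# expression timecourses with a planted upregulated subset. Seeds are
# mandatory; the caller's RNG state is left untouched.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Random background proteins
#'
#' Uniform-composition amino-acid sequences, used as the non-setae
#' background set in classifier experiments.
#'
#' @param n Number of proteins.
#' @param length Residues per protein.
#' @param seed Integer seed (mandatory).
#' @param prefix Id prefix (default `"bg"`).
#' @return Protein record data frame (see [protein_records()]).
#' @export
random_proteins <- function(n, length = 120, seed, prefix = "bg") {
  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
    }, character(1))
    protein_records(sprintf("%s%04d", prefix, seq_len(n)), seqs, "background")
  })
}

# evolve an amino-acid sequence for dt Myr: site-wise Poisson substitution
# at rate `rates[i]` per site per Myr, equal probability over the other
# 19 residues at each jump
.evolve_protein <- function(chars, rates, dt) {
  k <- rpois(length(chars), rates * dt)
  hit <- which(k > 0L)
  for (i in hit) {
    for (j in seq_len(k[i])) {
      chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
    }
  }
  chars
}

#' Simulate a gene family by birth-death duplication
#'
#' Forward-time birth-death process over `time` Myr starting from a single
#' lineage: each lineage duplicates at rate `lambda` and is lost at rate
#' `mu`. Surviving lineages become leaves carrying protein sequences
#' evolved site-wise Poisson at `rate` substitutions/site/Myr; positions
#' in `motif_range` evolve at `motif_conservation * rate`, so
#' `motif_conservation = 0` freezes the core box. The ages (Myr before
#' present) of duplication nodes with two surviving descendant lineages
#' are returned as planted truth.
#'
#' @param lambda Duplication rate per lineage per Myr.
#' @param mu Loss rate per lineage per Myr.
#' @param time Total simulation time in Myr.
#' @param rate Clock rate, substitutions/site/Myr.
#' @param motif_conservation Factor in `[0, 1]` scaling the rate at motif
#'   positions.
#' @param root_protein Amino-acid sequence at the root. The default embeds
#'   the setae core box in a random background of `root_length` residues.
#' @param motif_range Integer positions of the motif within the root
#'   (computed automatically for the default root).
#' @param root_length Length of the default root protein.
#' @param seed Integer seed (mandatory).
#' @param prefix Leaf id prefix.
#' @param max_retries Retries when the whole family goes extinct.
#' @return List with `tree` ([ape::phylo], branch lengths in Myr;
#'   ultrametric over the surviving leaves), `records` (leaf proteins),
#'   `dup_ages` (numeric, Myr ago), `motif_range`, and `n_retries`.
#' @export
simulate_family <- function(lambda, mu, time, rate,
                            motif_conservation = 1,
                            root_protein = NULL, motif_range = NULL,
                            root_length = 120, seed, prefix = "fam",
                            max_retries = 100) {
  stopifnot(lambda >= 0, mu >= 0, time >= 0, rate >= 0,
            motif_conservation >= 0, motif_conservation <= 1)
  .with_seed(seed, {
    if (is.null(root_protein)) {
      motif <- SETAE_CORE_BOX
      bg_n <- root_length - nchar(motif)
      if (bg_n < 0) stop("root_length shorter than the core box")
      at <- sample(0:bg_n, 1L)
      bg <- sample(AA_STANDARD, bg_n, replace = TRUE)
      root_protein <- paste(c(head(bg, at), .aa_chars(motif),
                              tail(bg, bg_n - at)), collapse = "")
      motif_range <- (at + 1L):(at + nchar(motif))
    } else {
      root_protein <- .aa_check(root_protein)
      if (is.null(motif_range)) motif_range <- integer(0)
    }
    for (try in seq_len(max_retries)) {
      sim <- .simulate_bd(lambda, mu, time)
      if (!is.null(sim)) break
      sim <- NULL
    }
    if (is.null(sim)) stop("family extinct in every attempt (", max_retries, " retries)")

    rates <- rep(rate, nchar(root_protein))
    rates[motif_range] <- rate * motif_conservation
    leaf_seqs <- list()
    leaf_counter <- 0L
    dup_ages <- numeric(0)
    # walk the pruned lineage tree, evolving sequences branch by branch
    walk <- function(node, chars) {
      chars <- .evolve_protein(chars, rates, node$brlen)
      if (is.null(node$children)) {
        leaf_counter <<- leaf_counter + 1L
        id <- sprintf("%s%03d", prefix, leaf_counter)
        leaf_seqs[[id]] <<- paste(chars, collapse = "")
        return(sprintf("%s:%.8f", id, node$brlen))
      }
      dup_ages <<- c(dup_ages, time - node$time)
      kids <- vapply(node$children, walk, character(1),
                     chars = chars)
      sprintf("(%s):%.8f", paste(kids, collapse = ","), node$brlen)
    }
    nwk <- walk(sim, .aa_chars(root_protein))
    records <- protein_records(names(leaf_seqs), unlist(leaf_seqs),
                               "simulated family")
    tree <- if (length(leaf_seqs) >= 2L) {
      ape::read.tree(text = paste0(sub(":[0-9.]+$", "", nwk), ";"))
    } else NULL
    list(tree = tree, records = records,
         dup_ages = sort(dup_ages, decreasing = TRUE),
         motif_range = motif_range, n_retries = try - 1L)
  })
}

# forward birth-death simulation; returns the pruned surviving-lineage
# tree as nested lists (node: time of split, brlen from parent, children)
# or NULL if the family went extinct. Non-splitting chains are spliced
# out, so every internal node is a duplication with 2 surviving children.
.simulate_bd <- function(lambda, mu, time) {
  grow <- function(t0) {
    total <- lambda + mu
    w <- if (total > 0) rexp(1L, total) else Inf
    if (t0 + w >= time) {
      return(list(time = time, brlen = time - t0, children = NULL))
    }
    if (runif(1L) < lambda / total) {
      kids <- list(grow(t0 + w), grow(t0 + w))
      kids <- Filter(Negate(is.null), kids)
      if (!length(kids)) return(NULL)
      if (length(kids) == 1L) {
        # one side extinct: splice the dead duplication out
        k <- kids[[1L]]
        k$brlen <- k$brlen + (t0 + w - t0)
        return(k)
      }
      return(list(time = t0 + w, brlen = NA_real_, children = kids))
    }
    NULL  # lineage lost
  }
  root <- grow(0)
  if (is.null(root)) return(NULL)
  root$brlen <- if (is.na(root$brlen)) 0 else root$brlen
  fix <- function(node, t0) {
    if (is.null(node$children)) {
      node$brlen <- time - t0
      return(node)
    }
    node$brlen <- node$time - t0
    node$children <- lapply(node$children, fix, t0 = node$time)
    node
  }
  fix(root, 0)
}

#' Build an ultrametric tree with duplication nodes at planted ages
#'
#' Constructs a random rooted topology whose internal-node ages are
#' exactly the supplied values (Myr before present) and whose leaves sit
#' at age 0, i.e. an exactly clock-like duplication history. Branch
#' lengths are in Myr; multiply by a rate (see [scale_tree_branches()])
#' for a substitutions/site tree.
#'
#' @param node_ages Numeric vector of distinct internal-node ages in Myr;
#'   the oldest becomes the root.
#' @param seed Integer seed (mandatory).
#' @param prefix Leaf label prefix.
#' @return [ape::phylo] tree with `length(node_ages) + 1` leaves.
#' @export
simulate_burst_tree <- function(node_ages, seed, prefix = "dup") {
  stopifnot(length(node_ages) >= 1L, all(node_ages > 0),
            !anyDuplicated(node_ages))
  ages <- sort(node_ages, decreasing = TRUE)
  .with_seed(seed, {
    m <- length(ages)              # internal nodes
    ntip <- m + 1L
    # ape numbering: tips 1..ntip, internals ntip+1 .. ntip+m (root first)
    node_id <- ntip + seq_len(m)
    parent <- integer(0)
    child <- integer(0)
    length_myr <- numeric(0)
    slots <- c(node_id[1L], node_id[1L])   # open child slots (parent ids)
    slot_age <- c(ages[1L], ages[1L])
    if (m > 1L) {
      for (k in 2:m) {
        pick <- sample.int(length(slots), 1L)
        parent <- c(parent, slots[pick])
        child <- c(child, node_id[k])
        length_myr <- c(length_myr, slot_age[pick] - ages[k])
        slots <- slots[-pick]; slot_age <- slot_age[-pick]
        slots <- c(slots, node_id[k], node_id[k])
        slot_age <- c(slot_age, ages[k], ages[k])
      }
    }
    for (i in seq_along(slots)) {
      parent <- c(parent, slots[i])
      child <- c(child, i)               # tip ids 1..ntip in slot order
      length_myr <- c(length_myr, slot_age[i])
    }
    tree <- list(edge = cbind(parent, child),
                 edge.length = length_myr,
                 tip.label = sprintf("%s%03d", prefix, seq_len(ntip)),
                 Nnode = m)
    class(tree) <- "phylo"
    attr(tree, "order") <- NULL
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Scale tree branch lengths by a clock rate
#'
#' Converts a time tree (branches in Myr) to a substitutions/site tree
#' (branches `rate * Myr`) or back (`rate < 1` values work symmetrically).
#'
#' @param tree [ape::phylo] tree.
#' @param rate Multiplier (substitutions/site/Myr).
#' @return Tree with scaled branch lengths.
#' @export
scale_tree_branches <- function(tree, rate) {
  stopifnot(rate > 0)
  tree$edge.length <- tree$edge.length * rate
  tree
}

# ---- codon-pair simulator -------------------------------------------------

# static neighbour structure of the 61 sense codons: for each codon, its 9
# single-nucleotide neighbours with stop / synonymous / transition flags
.codon_neighbour_table <- function() {
  if (!is.null(.geckoevo_cache$nbr)) return(.geckoevo_cache$nbr)
  gc <- .genetic_code()
  sense <- .sense_codons()
  is_ts <- function(a, b) paste0(a, b) %in% c("AG", "GA", "CT", "TC")
  tab <- lapply(sense, function(cd) {
    nb <- .codon_neighbours(cd)
    pos <- rep(1:3, each = 3L)
    data.frame(
      target = nb,
      stop = gc[nb] == "*",
      syn = gc[nb] != "*" & gc[nb] == gc[[cd]],
      ts = vapply(seq_along(nb), function(i) {
        is_ts(substr(cd, pos[i], pos[i]), substr(nb[i], pos[i], pos[i]))
      }, logical(1)))
  })
  names(tab) <- sense
  .geckoevo_cache$nbr <- tab
  tab
}

#' Simulate a codon pair at a controlled dN/dS
#'
#' Mutation-selection rejection walk: starting from a random sense-codon
#' sequence, nucleotide changes are proposed with transition bias `kappa`,
#' proposals creating stop codons are rejected, and nonsynonymous
#' proposals are accepted with relative rate `omega`. Time is scaled so
#' one unit corresponds to about one substitution per codon site for the
#' average sense codon, and the walk runs for `t` units; the realised
#' synonymous/nonsynonymous substitution counts are returned as planted
#' truth, which makes the generator a valid oracle for [ng86_kaks()].
#'
#' @param omega Target dN/dS (>= 0).
#' @param kappa Transition/transversion rate ratio (default 1).
#' @param t Expected substitutions per codon site (>= 0).
#' @param length Sequence length in codons.
#' @param seed Integer seed (mandatory).
#' @return List with `alignment` (named character vector `anc`, `der`),
#'   `n_syn`, `n_nonsyn`, and the realised per-codon substitution count.
#' @export
simulate_codon_pair <- function(omega, kappa = 1, t, length = 300, seed) {
  stopifnot(omega >= 0, kappa > 0, t >= 0, length >= 1)
  .with_seed(seed, {
    nbr <- .codon_neighbour_table()
    sense <- .sense_codons()
    # per-codon neighbour weights under (kappa, omega)
    weights <- lapply(nbr, function(d) {
      w <- ifelse(d$stop, 0, ifelse(d$ts, kappa, 1) * ifelse(d$syn, 1, omega))
      w
    })
    codon_rate <- vapply(weights, sum, numeric(1))
    rho <- mean(codon_rate)  # normaliser: average sense codon = 1 sub/unit
    cur <- sample(sense, length, replace = TRUE)
    anc <- cur
    n_syn <- 0L
    n_nonsyn <- 0L
    t_cur <- 0
    repeat {
      rates <- codon_rate[cur] / rho
      total <- sum(rates)
      if (total <= 0) break
      t_cur <- t_cur + rexp(1L, total)
      if (t_cur > t) break
      i <- sample.int(length, 1L, prob = rates)
      d <- nbr[[cur[i]]]
      w <- weights[[cur[i]]]
      j <- sample.int(nrow(d), 1L, prob = w)
      if (d$syn[j]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      cur[i] <- d$target[j]
    }
    list(alignment = c(anc = paste(anc, collapse = ""),
                       der = paste(cur, collapse = "")),
         n_syn = n_syn, n_nonsyn = n_nonsyn)
  })
}

#' Simulate a set of ortholog alignments with planted selected genes
#'
#' Convenience wrapper around [simulate_codon_pair()]: `n_genes` two-way
#' ortholog alignments at background `omega_background`, with the named
#' subset simulated at `omega_selected`.
#'
#' @param n_genes Number of genes.
#' @param n_selected Number of planted positively selected genes.
#' @param omega_background,omega_selected dN/dS of the two classes.
#' @param t Divergence, substitutions per codon site.
#' @param length Codons per gene (default 500, the typical length of a
#'   vertebrate single-copy ortholog CDS; at this length the planted and
#'   background Ka/Ks distributions are well separated at `t = 0.3`).
#' @param seed Integer seed (mandatory).
#' @param focal,comparator Sequence names used in each alignment.
#' @return List with `orthologs` (named list of alignments), `selected`
#'   (planted gene ids) and `truth` (per-gene data frame).
#' @export
simulate_ortholog_set <- function(n_genes = 50, n_selected = 5,
                                  omega_background = 0.2, omega_selected = 3,
                                  t = 0.3, length = 500, seed,
                                  focal = "gecko", comparator = "anolis") {
  stopifnot(n_selected <= n_genes)
  .with_seed(seed, {
    ids <- sprintf("gene%03d", seq_len(n_genes))
    selected <- sort(sample(ids, n_selected))
    seeds <- sample.int(.Machine$integer.max, n_genes)
    orthologs <- list()
    for (k in seq_len(n_genes)) {
      om <- if (ids[k] %in% selected) omega_selected else omega_background
      sim <- simulate_codon_pair(om, kappa = 1, t = t, length = length,
                                 seed = seeds[k])
      aln <- sim$alignment
      names(aln) <- c(focal, comparator)
      orthologs[[ids[k]]] <- aln
    }
    truth <- data.frame(gene = ids,
                        omega = ifelse(ids %in% selected,
                                       omega_selected, omega_background),
                        selected = ids %in% selected)
    list(orthologs = orthologs, selected = selected, truth = truth)
  })
}

# ---- disruption injection -------------------------------------------------

# map a 1-based CDS position to its 1-based genomic position
.cds_to_genomic <- function(model, pos) {
  lens <- model$exons[, "end"] - model$exons[, "start"]
  stopifnot(pos >= 1L, pos <= sum(lens))
  cum <- cumsum(lens)
  ex <- which(pos <= cum)[1L]
  off <- pos - c(0L, cum)[ex]   # 1-based offset within exon (transcript sense)
  if (model$strand == "+") {
    model$exons[ex, "start"] + off
  } else {
    model$exons[ex, "end"] - off + 1L
  }
}

.set_base <- function(contig, gpos, base, strand) {
  if (strand == "-") base <- chartr("ACGT", "TGCA", base)
  substr(contig, gpos, gpos) <- base
  contig
}

#' Inject ORF/exon disruptions into a gene model
#'
#' Applies a set of requested defects exactly once each and returns the
#' mutated contig, the (possibly updated) gene model and a truth record.
#' Supported defects:
#' * `list(type = "start_loss")` - first CDS base substituted so the
#'   initiation codon is no longer ATG;
#' * `list(type = "stop_loss")` - last CDS base substituted so the
#'   termination codon is no longer a stop;
#' * `list(type = "frameshift", pos = <cds position>)` - 1-bp insertion
#'   after the given CDS position (plus-strand models only);
#' * `list(type = "delete_exon", exon = <i>)` - exon removed from the model;
#' * `list(type = "shift_exon", exon = <i>, by = <k>)` - the exon's start
#'   boundary moved by `k` bp, changing its length (a non-multiple of 3
#'   shifts the downstream reading frame).
#'
#' @param model A [gene_model()].
#' @param contig Contig nucleotide sequence.
#' @param defects List of defect specifications (see above).
#' @return List with `model`, `contig` and `truth` (data frame `type`,
#'   `detail`).
#' @export
inject_disruptions <- function(model, contig, defects) {
  contig <- .dna_check(contig)
  truth <- data.frame(type = character(0), detail = character(0))
  edited <- integer(0)  # CDS positions touched, for conflict detection
  mark <- function(pos) {
    if (pos %in% edited) stop("conflicting edits at CDS position ", pos)
    edited <<- c(edited, pos)
  }
  for (d in defects) {
    type <- d$type
    if (type == "start_loss") {
      mark(1L)
      g <- .cds_to_genomic(model, 1L)
      contig <- .set_base(contig, g, "C", model$strand)
      truth <- rbind(truth, data.frame(type = type, detail = "cds:1"))
    } else if (type == "stop_loss") {
      lens <- sum(model$exons[, "end"] - model$exons[, "start"])
      mark(lens)
      g <- .cds_to_genomic(model, lens)
      contig <- .set_base(contig, g, "C", model$strand)
      truth <- rbind(truth, data.frame(type = type, detail = paste0("cds:", lens)))
    } else if (type == "frameshift") {
      if (model$strand != "+") stop("frameshift injection supports plus-strand models")
      mark(d$pos)
      g <- .cds_to_genomic(model, d$pos)
      contig <- paste0(substr(contig, 1L, g), "A",
                       substr(contig, g + 1L, nchar(contig)))
      ex <- model$exons
      hit <- which(g > ex[, "start"] & g <= ex[, "end"])[1L]
      ex[hit, "end"] <- ex[hit, "end"] + 1L
      if (hit < nrow(ex)) {
        later <- (hit + 1L):nrow(ex)
        ex[later, ] <- ex[later, ] + 1L
      }
      model$exons <- ex
      truth <- rbind(truth, data.frame(type = type, detail = paste0("cds:", d$pos)))
    } else if (type == "delete_exon") {
      stopifnot(d$exon >= 1L, d$exon <= nrow(model$exons))
      model$exons <- model$exons[-d$exon, , drop = FALSE]
      truth <- rbind(truth, data.frame(type = type, detail = paste0("exon:", d$exon)))
    } else if (type == "shift_exon") {
      stopifnot(d$exon >= 1L, d$exon <= nrow(model$exons))
      ex <- model$exons
      ex[d$exon, "start"] <- ex[d$exon, "start"] + as.integer(d$by)
      if (ex[d$exon, "start"] < 0L || ex[d$exon, "start"] >= ex[d$exon, "end"]) {
        stop("shift_exon moves the boundary out of range")
      }
      model$exons <- ex
      truth <- rbind(truth, data.frame(
        type = type, detail = sprintf("exon:%d by:%d", d$exon, d$by)))
    } else {
      stop("unknown defect type: ", type)
    }
  }
  list(model = model, contig = contig, truth = truth)
}

#' Simulate a functional multi-exon gene and its contig
#'
#' Builds a random intact ORF (ATG ... stop, no internal stops), splits it
#' into exons separated by random introns, and embeds it in a contig.
#' Useful as the functional reference and as the template that
#' [inject_disruptions()] mutates.
#'
#' @param n_exons Number of exons.
#' @param exon_length Approximate exon length in bp (multiples of 1).
#' @param intron_length Intron length in bp.
#' @param flank Flanking sequence length on each side.
#' @param seed Integer seed (mandatory).
#' @param id Gene id.
#' @return List with `model` ([gene_model()]), `contig`, `cds` and
#'   `exon_lengths`.
#' @export
simulate_gene <- function(n_exons = 3, exon_length = 120, intron_length = 60,
                          flank = 30, seed, id = "gene1") {
  .with_seed(seed, {
    sense <- setdiff(.sense_codons(), "ATG")
    total <- n_exons * exon_length
    ncod <- total %/% 3L
    body <- sample(sense, ncod - 2L, replace = TRUE)
    cds <- paste(c("ATG", body, "TAA"), collapse = "")
    cds_len <- nchar(cds)
    base_len <- cds_len %/% n_exons
    exon_lengths <- rep(base_len, n_exons)
    exon_lengths[n_exons] <- cds_len - base_len * (n_exons - 1L)
    rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
    pos <- flank
    exons <- matrix(0L, n_exons, 2L)
    pieces <- rand_dna(flank)
    ends <- cumsum(exon_lengths)
    starts <- ends - exon_lengths + 1L
    for (i in seq_len(n_exons)) {
      exons[i, ] <- c(pos, pos + exon_lengths[i])
      pieces <- paste0(pieces, substring(cds, starts[i], ends[i]))
      pos <- pos + exon_lengths[i]
      if (i < n_exons) {
        pieces <- paste0(pieces, rand_dna(intron_length))
        pos <- pos + intron_length
      }
    }
    pieces <- paste0(pieces, rand_dna(flank))
    list(model = gene_model(id, exons, "+", "synthetic_contig"),
         contig = pieces, cds = cds, exon_lengths = exon_lengths)
  })
}

# ---- expression table -----------------------------------------------------

#' Simulate a post-autotomy expression timecourse
#'
#' Log-normal day-0 baselines; each planted gene is multiplied by at least
#' `fold` at one random post-autotomy timepoint (1, 3 or 7 days); all
#' other values fluctuate around baseline with coefficient of variation
#' `noise_cv`. With `noise_cv = 0`, [expression_overlap()] at threshold
#' `fold` recovers the planted fraction exactly.
#'
#' @param n_genes Number of genes (ids `g001`, `g002`, ...).
#' @param planted_up_ids Ids of genes to upregulate (subset of the gene
#'   set), or an integer count (the first so-many genes after a seeded
#'   shuffle).
#' @param fold Planted fold change (> 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed (mandatory).
#' @return List with `table` (data frame `gene`, `d0`, `d1`, `d3`, `d7`)
#'   and `planted` (character ids).
#' @export
simulate_expression <- function(n_genes, planted_up_ids, fold = 2,
                                noise_cv = 0, seed) {
  stopifnot(fold > 1, noise_cv >= 0)
  .with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n_genes))
    if (is.numeric(planted_up_ids) && length(planted_up_ids) == 1L) {
      planted <- sort(sample(ids, planted_up_ids))
    } else {
      planted <- as.character(planted_up_ids)
      if (!all(planted %in% ids)) stop("planted ids must be within the gene set")
    }
    d0 <- rlnorm(n_genes, meanlog = 3, sdlog = 0.8)
    noisy <- function(x) x * pmax(0, 1 + rnorm(length(x)) * noise_cv)
    tab <- data.frame(gene = ids, d0 = d0,
                      d1 = noisy(d0), d3 = noisy(d0), d7 = noisy(d0))
    later <- c("d1", "d3", "d7")
    for (g in planted) {
      tp <- sample(later, 1L)
      i <- match(g, ids)
      tab[i, tp] <- tab$d0[i] * fold * (1 + abs(rnorm(1L)) * noise_cv)
    }
    list(table = tab, planted = planted)
  })
}

#' Write a truth sidecar table
#'
#' @param truth Data frame of planted ground truth.
#' @param path Output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
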