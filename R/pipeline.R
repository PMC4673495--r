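# Orchestration of the three analyses (setae keratins, vision/olfaction,
# regeneration) with flat-file handoff: every stage reads and writes
# plain FASTA/newick/TSV so intermediate artefacts stay inspectable, all
# outputs are written atomically (temp file + rename), and each table
# carries a header naming the tool version and the resolved parameters.

.pkg_version <- function() {
  as.character(utils::packageVersion("geckoevo"))
}

# atomic TSV write with a commented provenance header
.write_tsv_atomic <- function(df, path, params = list()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(sprintf("# geckoevo %s", .pkg_version()), con)
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(v)
      paste(format(v), collapse = ","), character(1)), sep = "=")
    writeLines(paste0("# params: ", paste(kv, collapse = "; ")), con)
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an aligned FASTA file as a named character vector
#'
#' @param path FASTA path (nucleotide or amino acid).
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_alignment_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  xs <- if (type == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
}

#' Read per-gene ortholog alignments from a directory
#'
#' One aligned CDS FASTA per gene (`<gene>.fa`/`.fasta`); frame validity
#' (length divisible by 3) is checked on read.
#'
#' @param dir Directory of FASTA files.
#' @return Named list of named character vectors.
#' @export
read_ortholog_fasta_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files found in ", dir)
  out <- lapply(files, function(f) {
    aln <- read_alignment_fasta(f, "DNA")
    if (unique(nchar(aln)) %% 3L != 0L) {
      stop("alignment in ", basename(f), " is not frame-valid")
    }
    aln
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}

#' Run the setae beta-keratin analysis
#'
#' Classifies every protein with the five-feature core-box classifier,
#' builds (or loads) a tree, fits a strict-clock rate from the
#' calibrations, and dates the expansion bursts of the core-box (flag 1)
#' clade. When no calibrations are supplied, dating is skipped with a
#' warning and the classification is still emitted.
#'
#' @param records Protein records (data frame), or a FASTA path.
#' @param out_dir Output directory (created if needed).
#' @param tree Optional [ape::phylo] tree or newick path (branch lengths
#'   in substitutions/site). When absent, a tree is built from the
#'   alignment of the sequences if they are aligned (equal length), else
#'   dating is skipped.
#' @param calibrations List of [calibration_point()] objects, or a
#'   calibration config path (see [read_calibrations()]), or `NULL`.
#' @param motif,thresholds Classifier settings, see [classify_keratin()].
#' @param distance_model Distance for tree building, see
#'   [pairwise_distance()].
#' @param max_gap Burst segmentation gap in Myr (default 5).
#' @return Invisibly, a list with `classification`, `summary`, `fit` and
#'   `expansion`; files `classification.tsv`, `family_summary.tsv` and
#'   (when dated) `expansion_nodes.tsv`, `expansion_bursts.tsv` are
#'   written under `out_dir`.
#' @export
run_keratin_analysis <- function(records, out_dir, tree = NULL,
                                 calibrations = NULL,
                                 motif = SETAE_CORE_BOX,
                                 thresholds = keratin_thresholds(),
                                 distance_model = "poisson",
                                 max_gap = 5) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_protein_fasta(records)
  }
  if (!nrow(records)) stop("no protein records supplied")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(motif = motif, min_identity = thresholds$min_identity,
                 cys = thresholds$cys, gly = thresholds$gly,
                 pi = thresholds$pi, max_mw = thresholds$max_mw,
                 distance_model = distance_model, max_gap = max_gap)

  profiles <- classify_keratins(records, motif = motif, thresholds = thresholds)
  cls <- keratin_profile_table(profiles)
  fam <- summarize_family(profiles)
  .write_tsv_atomic(cls, file.path(out_dir, "classification.tsv"), params)
  .write_tsv_atomic(
    data.frame(flag = names(fam$flag_counts), count = as.integer(fam$flag_counts)),
    file.path(out_dir, "family_summary.tsv"), params)

  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.character(calibrations)) calibrations <- read_calibrations(calibrations)
  if (is.null(tree)) {
    widths <- unique(nchar(records$sequence))
    if (length(widths) == 1L && nrow(records) >= 3L) {
      d <- pairwise_distance(setNames(records$sequence, records$id),
                             model = distance_model)
      tree <- neighbor_joining(d)
    }
  }
  fit <- NULL
  expansion <- NULL
  if (is.null(calibrations) || !length(calibrations)) {
    warning("no calibration points: expansion dating skipped")
  } else if (is.null(tree)) {
    warning("no tree available: expansion dating skipped")
  } else {
    fit <- fit_rate(tree, calibrations)
    setae_ids <- cls$id[grepl("(^|,)1(,|$)", cls$flags)]
    expansion <- date_expansions(tree, fit$rate, setae_ids, max_gap = max_gap)
    .write_tsv_atomic(expansion$ages,
                      file.path(out_dir, "expansion_nodes.tsv"),
                      c(params, rate = fit$rate))
    .write_tsv_atomic(expansion$bursts,
                      file.path(out_dir, "expansion_bursts.tsv"),
                      c(params, rate = fit$rate))
  }
  invisible(list(classification = cls, summary = fam, fit = fit,
                 expansion = expansion))
}

#' Run the vision/olfaction analysis
#'
#' Scans candidate gene models for ORF/exon disruptions against their
#' functional references (pseudogene calling) and assigns query sequences
#' to labelled subgroups by reference placement, with per-subgroup counts.
#' Per-gene failures are logged and the run continues.
#'
#' @param candidates Named list; each element is a list with `model`
#'   ([gene_model()]), `contig`, `ref_cds` and `ref_exon_lengths`.
#' @param out_dir Output directory.
#' @param queries Named character vector of query sequences (optional).
#' @param references Named character vector of aligned reference
#'   sequences (required with `queries`).
#' @param labels Subgroup labels, one per reference.
#' @param identity_floor,coverage_floor See [compare_to_functional()].
#' @param seq_type `"AA"` or `"DNA"` for placement.
#' @return Invisibly, list with `disruptions` (reports), `placements` and
#'   `class_counts`; files `disruptions.tsv`, `placements.tsv`,
#'   `class_counts.tsv` under `out_dir`.
#' @export
run_vision_olfaction_analysis <- function(candidates, out_dir,
                                          queries = NULL, references = NULL,
                                          labels = NULL,
                                          identity_floor = 50,
                                          coverage_floor = 0.8,
                                          seq_type = "DNA") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(identity_floor = identity_floor,
                 coverage_floor = coverage_floor)
  reports <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    reports[[nm]] <- tryCatch(
      compare_to_functional(cand$model, cand$contig, cand$ref_cds,
                            cand$ref_exon_lengths,
                            identity_floor = identity_floor,
                            coverage_floor = coverage_floor),
      error = function(e) {
        message("pseudogene scan failed for ", nm, ": ", conditionMessage(e))
        NULL
      })
  }
  reports <- Filter(Negate(is.null), reports)
  if (length(reports)) {
    .write_tsv_atomic(disruption_table(reports),
                      file.path(out_dir, "disruptions.tsv"), params)
  }
  placements <- NULL
  counts <- NULL
  if (!is.null(queries)) {
    stopifnot(!is.null(references), !is.null(labels))
    placements <- do.call(rbind, lapply(names(queries), function(q) {
      res <- classify_by_placement(queries[[q]], references, labels,
                                   seq_type = seq_type)
      data.frame(query = q, label = res$label,
                 support = res$support, nearest = res$nearest)
    }))
    counts <- as.data.frame(table(label = placements$label),
                            responseName = "count")
    .write_tsv_atomic(placements, file.path(out_dir, "placements.tsv"), params)
    .write_tsv_atomic(counts, file.path(out_dir, "class_counts.tsv"), params)
  }
  invisible(list(disruptions = reports, placements = placements,
                 class_counts = counts))
}

#' Run the tail-regeneration selection analysis
#'
#' Filters each ortholog alignment, estimates pairwise NG86 Ka/Ks,
#' screens for positively selected genes (ratio above threshold) and
#' computes the fraction of candidates upregulated after autotomy.
#'
#' @param orthologs Named list of per-gene codon alignments, or a
#'   directory of per-gene FASTA files.
#' @param focal Focal-species sequence name.
#' @param expression Expression table (data frame or TSV path), or `NULL`
#'   to skip the overlap step.
#' @param out_dir Output directory.
#' @param threshold Ka/Ks candidate threshold (default 1).
#' @param fold_threshold Upregulation fold threshold (default 2).
#' @param min_codons Minimum compared codons (default 30).
#' @param filter Apply [filter_blocks()] (default TRUE).
#' @return Invisibly, list with `screen` (see [screen_psg()]) and
#'   `overlap`; files `psg_table.tsv` and `overlap_summary.tsv` under
#'   `out_dir`. An empty candidate table yields an explicit 0/0 overlap
#'   row flagged `no_candidates`.
#' @export
run_regeneration_analysis <- function(orthologs, focal, expression, out_dir,
                                      threshold = 1, fold_threshold = 2,
                                      min_codons = 30, filter = TRUE) {
  if (is.character(orthologs) && length(orthologs) == 1L) {
    orthologs <- read_ortholog_fasta_dir(orthologs)
  }
  if (is.character(expression) && length(expression) == 1L) {
    expression <- read_expression_table(expression)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(focal = focal, threshold = threshold,
                 fold_threshold = fold_threshold, min_codons = min_codons)
  screen <- screen_psg(orthologs, focal, threshold = threshold,
                       min_codons = min_codons, filter = filter)
  .write_tsv_atomic(screen$psg, file.path(out_dir, "psg_table.tsv"), params)
  overlap <- NULL
  if (!is.null(expression)) {
    if (nrow(screen$psg)) {
      overlap <- expression_overlap(screen$psg$gene, expression,
                                    fold_threshold = fold_threshold)
      flag <- "ok"
    } else {
      overlap <- list(numerator = 0L, denominator = 0L, fraction = NA_real_,
                      missing = character(0))
      flag <- "no_candidates"
    }
    .write_tsv_atomic(
      data.frame(upregulated = overlap$numerator,
                 candidates = overlap$denominator,
                 fraction = overlap$fraction, flag = flag),
      file.path(out_dir, "overlap_summary.tsv"), params)
  }
  invisible(list(screen = screen, overlap = overlap))
}
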