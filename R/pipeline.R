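# Stage orchestration: each run_* function reads its inputs through
# io_formats, executes one pipeline stage, writes TSV outputs plus a JSON
# manifest (package version, config hash, input checksums, seed) into the
# output directory, and returns its results invisibly for programmatic use.

.default_params <- function() {
  list(min_length = 1000, min_individuals = 2, reciprocal_frac = 0.5,
       top_fraction = 0.01, upstream_bp = 1000, downstream_bp = 1000,
       splice_bp = 2, min_overlap_bp = 1, min_overlap_frac = 0)
}

#' Load and validate a pipeline run configuration
#'
#' YAML with two blocks: `paths` (sample_sheet, genome, gene_models,
#' qtl_table, published_cnvrs, out_dir) and `params` (min_length,
#' min_individuals, reciprocal_frac, top_fraction, upstream_bp,
#' downstream_bp, splice_bp, min_overlap_bp, min_overlap_frac), plus
#' `pop_pairs` (list of 2-element population-id vectors) and `seed`.
#' Omitted parameters take the documented defaults; referenced input paths
#' must exist.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return a validated `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$paths)) cfg$paths <- list()
  params <- utils::modifyList(.default_params(),
                              if (is.null(cfg$params)) list()
                              else cfg$params)
  bad <- names(params)[!names(params) %in% names(.default_params())]
  if (length(bad))
    .stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  if (params$reciprocal_frac <= 0 || params$reciprocal_frac > 1)
    .stopf("reciprocal_frac must be in (0, 1]")
  if (params$top_fraction <= 0 || params$top_fraction > 1)
    .stopf("top_fraction must be in (0, 1]")
  if (params$min_length < 0) .stopf("min_length must be >= 0")
  cfg$params <- params
  if (is.null(cfg$seed)) cfg$seed <- 1L
  for (key in c("sample_sheet", "genome", "gene_models", "qtl_table",
                "published_cnvrs")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      .stopf("configured path %s does not exist: %s", key, p)
  }
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonicalised config; file checksums for the manifest
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg)[sort(names(unclass(cfg)))], tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(out_dir, stage, cfg, inputs = character(0)) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(
    tool = "cnvrpop",
    version = as.character(utils::packageVersion("cnvrpop")),
    stage = stage,
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    input_checksums = checksums
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.load_cohort_calls <- function(cfg) {
  sheet <- read_sample_sheet(cfg$paths$sample_sheet)
  if (is.null(sheet$path))
    .stopf("sample sheet must carry a 'path' column with call files")
  fmt <- if (is.null(sheet$format)) rep("cnvnator", nrow(sheet))
         else sheet$format
  parts <- lapply(seq_len(nrow(sheet)), function(i) {
    reader <- switch(tolower(fmt[[i]]),
                     cnvnator = read_cnvnator_calls,
                     bed = read_bed_calls,
                     .stopf("unknown call format: %s", fmt[[i]]))
    reader(sheet$path[[i]], sheet$sample_id[[i]], sheet$population_id[[i]])
  })
  list(calls = bind_calls(parts), samples = sheet)
}

#' Stage 1: simulate a synthetic cohort to disk
#'
#' Runs [simulate_cohort()] with the config seed and writes call files,
#' sample sheet, genome and truth via [write_sim_cohort()], plus a run
#' manifest. Rerunning with the same config reproduces identical outputs.
#'
#' @param cfg a [run_config] (uses `paths$out_dir` and `seed`; optional
#'   `sim` block with [sim_config()] fields).
#' @return the `sim_cohort`, invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- run_config(cfg)
  out_dir <- cfg$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- if (is.null(cfg$sim)) list() else cfg$sim
  sim_args$seed <- cfg$seed
  sim <- simulate_cohort(do.call(sim_config, sim_args))
  write_sim_cohort(sim, out_dir)
  .write_manifest(out_dir, "simulate", cfg)
  invisible(sim)
}

#' Stage 2: build breed and cohort CNVRs
#'
#' Reads the per-sample call files from the sample sheet, applies the
#' length and placement filters, the within-population recurrence filter,
#' breed-level and cohort-level reciprocal-overlap merging, and writes
#' breed/cohort CNVR BEDs, a per-breed summary table, the cohort length
#' histogram, drop counts (JSON sidecar) and a manifest.
#'
#' @param cfg a [run_config]; needs `paths$sample_sheet`, `paths$genome`,
#'   `paths$out_dir`.
#' @return list with `cohort` (`cnvr_set`), `breed_sets`, `samples`,
#'   `calls`, invisibly.
#' @export
run_cnvr <- function(cfg) {
  cfg <- run_config(cfg)
  out_dir <- cfg$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_chrom_sizes(cfg$paths$genome)
  loaded <- .load_cohort_calls(cfg)
  p <- cfg$params

  filt <- filter_calls(loaded$calls, genome, min_length = p$min_length)
  recurrent <- recurrence_filter(filt$calls,
                                 min_individuals = p$min_individuals,
                                 match_frac = p$reciprocal_frac)
  breed_sets <- build_breed_cnvrs(recurrent, genome,
                                  frac = p$reciprocal_frac)
  cohort <- if (length(breed_sets) > 0L)
    merge_breed_to_cohort(breed_sets, genome, frac = p$reciprocal_frac)
  else
    merge_reciprocal(recurrent, genome, frac = p$reciprocal_frac,
                     level = "COHORT")
  if (nrow(cohort$cnvrs) == 0L)
    .warnf("no CNVRs survived filtering and merging")

  for (b in names(breed_sets))
    write_cnvr_bed(breed_sets[[b]],
                   file.path(out_dir, sprintf("breed_%s_cnvrs.bed", b)),
                   genome)
  write_cnvr_bed(cohort, file.path(out_dir, "cohort_cnvrs.bed"), genome)
  if (length(breed_sets) > 0L)
    .tsv(cnvr_summary_table(breed_sets, loaded$samples, genome),
         file.path(out_dir, "breed_summary.tsv"))
  .tsv(summarize_cnvrs(cohort, genome),
       file.path(out_dir, "cohort_summary.tsv"))
  .tsv(length_histogram(cohort),
       file.path(out_dir, "cohort_length_histogram.tsv"))
  counts <- list(
    n_input_calls = nrow(loaded$calls),
    n_reader_errors = nrow(call_errors(loaded$calls)),
    drop_report = filt$drop_report,
    n_after_filters = nrow(filt$calls),
    n_after_recurrence = nrow(recurrent),
    n_breed_cnvrs = vapply(breed_sets, function(s) nrow(s$cnvrs),
                           integer(1)),
    n_cohort_cnvrs = nrow(cohort$cnvrs)
  )
  jsonlite::write_json(counts, file.path(out_dir, "cnvr_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "cnvr", cfg,
                  c(cfg$paths$sample_sheet, cfg$paths$genome))
  invisible(list(cohort = cohort, breed_sets = breed_sets,
                 samples = loaded$samples, calls = loaded$calls))
}

#' Stage 3: pairwise Vst and top-percentile selection
#'
#' Builds the autosomal copy-number matrix, computes per-CNVR Vst for each
#' configured population pair, selects the empirical top fraction per
#' pair, and writes per-pair Vst TSVs (Manhattan-ready: chrom, start, end,
#' vst, selected), a threshold report, selected-CNVR lists, and — when
#' gene models are configured — per-pair selected gene lists and their
#' across-pair intersection.
#'
#' @param cfg a [run_config]; needs `pop_pairs`.
#' @param cnvr_result the output of [run_cnvr()] (recomputed from `cfg`
#'   when omitted).
#' @return list with `records` (per-pair Vst tables), `thresholds`,
#'   `gene_sets`, `intersection`, invisibly.
#' @export
run_vst <- function(cfg, cnvr_result = NULL) {
  cfg <- run_config(cfg)
  out_dir <- cfg$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_chrom_sizes(cfg$paths$genome)
  if (is.null(cnvr_result)) cnvr_result <- run_cnvr(cfg)
  if (is.null(cfg$pop_pairs) || length(cfg$pop_pairs) == 0L)
    .stopf("no population pairs configured for Vst")
  models <- if (!is.null(cfg$paths$gene_models))
    read_gene_models(cfg$paths$gene_models) else NULL

  mat <- build_cn_matrix(cnvr_result$cohort, cnvr_result$calls,
                         cnvr_result$samples, genome)
  records <- list(); thresholds <- list(); gene_sets <- list()
  for (pair in cfg$pop_pairs) {
    key <- paste(pair, collapse = "_vs_")
    rec <- tryCatch(
      pairwise_vst(mat, pair[[1L]], pair[[2L]]),
      error = function(e) {
        .warnf("pair %s skipped: %s", key, conditionMessage(e))
        NULL
      })
    if (is.null(rec)) next
    rec <- select_differentiated(rec, top_fraction = cfg$params$top_fraction)
    thr <- attr(rec, "threshold")
    records[[key]] <- rec
    thresholds[[key]] <- data.frame(pair = key, n = thr$n, k = thr$k,
                                    threshold = thr$threshold)
    .tsv(rec, file.path(out_dir, sprintf("vst_%s.tsv", key)))
    sel <- rec[rec$selected, , drop = FALSE]
    .tsv(sel, file.path(out_dir, sprintf("vst_%s_selected.tsv", key)))
    if (!is.null(models)) {
      genes <- overlapping_genes(
        cnvr_result$cohort$cnvrs[
          cnvr_result$cohort$cnvrs$cnvr_id %in% sel$cnvr_id, ,
          drop = FALSE], models)
      gene_sets[[key]] <- genes
      writeLines(genes,
                 file.path(out_dir, sprintf("genes_%s_selected.txt", key)))
    }
  }
  if (length(thresholds))
    .tsv(do.call(rbind, thresholds),
         file.path(out_dir, "vst_thresholds.tsv"))
  intersection <- NULL
  if (length(gene_sets) >= 2L) {
    intersection <- intersect_comparisons(gene_sets)
    writeLines(intersection$common,
               file.path(out_dir, "genes_selected_all_pairs.txt"))
  }
  .write_manifest(out_dir, "vst", cfg,
                  c(cfg$paths$sample_sheet, cfg$paths$genome,
                    cfg$paths$gene_models))
  invisible(list(records = records, thresholds = thresholds,
                 gene_sets = gene_sets, intersection = intersection,
                 matrix = mat))
}

#' Stage 4: positional annotation and overlap reports
#'
#' Annotates the cohort CNVRs against gene models (category + overlapping
#' genes), partitions per-breed CNVR-harboring gene sets into common and
#' breed-specific sets, and counts overlaps with QTL traits and published
#' CNVR sets when those tables are configured.
#'
#' @param cfg a [run_config].
#' @param cnvr_result the output of [run_cnvr()] (recomputed when
#'   omitted).
#' @return list with `annotation`, `gene_partition`, `qtl_report`,
#'   `published_report`, invisibly.
#' @export
run_annotate <- function(cfg, cnvr_result = NULL) {
  cfg <- run_config(cfg)
  out_dir <- cfg$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_chrom_sizes(cfg$paths$genome)
  if (is.null(cnvr_result)) cnvr_result <- run_cnvr(cfg)
  p <- cfg$params

  annotation <- NULL; partition <- NULL
  if (!is.null(cfg$paths$gene_models)) {
    models <- read_gene_models(cfg$paths$gene_models)
    annotation <- annotate_context(cnvr_result$cohort, models,
                                   upstream_bp = p$upstream_bp,
                                   downstream_bp = p$downstream_bp,
                                   splice_bp = p$splice_bp)
    .tsv(annotation, file.path(out_dir, "cohort_annotation.tsv"))
    breed_genes <- lapply(cnvr_result$breed_sets, overlapping_genes,
                          models = models)
    if (length(breed_genes) >= 2L) {
      partition <- gene_set_partition(breed_genes)
      writeLines(partition$common,
                 file.path(out_dir, "genes_common_all_breeds.txt"))
      for (b in names(partition$specific))
        writeLines(partition$specific[[b]],
                   file.path(out_dir,
                             sprintf("genes_specific_%s.txt", b)))
    }
  }
  reports <- list(qtl_report = NULL, published_report = NULL)
  for (spec in list(c("qtl_table", "QTL", "qtl"),
                    c("published_cnvrs", "PUBLISHED_CNVR", "published"))) {
    if (is.null(cfg$paths[[spec[[1L]]]])) next
    intervals <- read_interval_table(cfg$paths[[spec[[1L]]]], genome,
                                     kind = spec[[2L]])
    rep <- interval_overlap_report(cnvr_result$cohort, intervals,
                                   min_overlap_bp = p$min_overlap_bp,
                                   min_overlap_frac = p$min_overlap_frac)
    .tsv(rep$per_label,
         file.path(out_dir, sprintf("overlap_%s_per_label.tsv",
                                    spec[[3L]])))
    .tsv(rep$per_cnvr,
         file.path(out_dir, sprintf("overlap_%s_per_cnvr.tsv",
                                    spec[[3L]])))
    reports[[paste0(spec[[3L]], "_report")]] <- rep
  }
  .write_manifest(out_dir, "annotate", cfg,
                  unlist(cfg$paths[c("sample_sheet", "genome",
                                     "gene_models", "qtl_table",
                                     "published_cnvrs")]))
  invisible(list(annotation = annotation, gene_partition = partition,
                 qtl_report = reports$qtl_report,
                 published_report = reports$published_report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
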