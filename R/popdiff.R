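#' Per-sample copy numbers over autosomal cohort CNVRs
#'
#' For each autosomal cohort CNVR and each sample, the cell value is the
#' coverage-length-weighted mean copy number of the sample's calls over the
#' region, with bases not covered by any call contributing the diploid
#' baseline 2. A sample with no overlapping call therefore gets exactly
#' 2.0. All calls of a sample are used (not only those that became CNVR
#' members), since any overlapping call carries read-depth information.
#'
#' @param cohort a cohort-level `cnvr_set` (see [merge_breed_to_cohort()]).
#' @param calls the full `cnv_calls` table (any chromosome; only calls
#'   overlapping autosomal CNVRs contribute).
#' @param samples sample sheet data.frame (`sample_id`, `population_id`);
#'   every sample appearing in `calls` must be listed.
#' @param genome a [genome_def]; only CNVRs on `genome$autosome_set` enter
#'   the matrix.
#' @return an object of class `cn_matrix`: list with `cn` (numeric matrix,
#'   CNVR rows in genome order, sample columns), `cnvrs` (the autosomal
#'   CNVR table) and `samples` (the sample sheet).
#' @export
build_cn_matrix <- function(cohort, calls, samples, genome) {
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown))
    .stopf("calls reference sample(s) absent from the sample sheet: %s",
           paste(unknown, collapse = ", "))
  cnvrs <- cohort$cnvrs[cohort$cnvrs$chrom %in% genome$autosome_set, ,
                        drop = FALSE]
  cnvrs <- .sort_intervals(cnvrs, genome)
  rownames(cnvrs) <- NULL
  cn <- matrix(2, nrow = nrow(cnvrs), ncol = nrow(samples),
               dimnames = list(cnvrs$cnvr_id, samples$sample_id))
  if (nrow(cnvrs) > 0L && nrow(calls) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(cnvrs),
                                        .as_granges(calls))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      ov <- .ov_len(cnvrs$start[qi], cnvrs$end[qi],
                    calls$start[si], calls$end[si])
      key <- split(data.frame(q = qi, cn = calls$copy_number[si], ov = ov,
                              sample = calls$sample_id[si]),
                   list(qi, calls$sample_id[si]), drop = TRUE)
      for (grp in key) {
        q <- grp$q[[1L]]
        L <- cnvrs$end[[q]] - cnvrs$start[[q]]
        covered <- sum(grp$ov)
        # calls of one sample are expected not to overlap each other; if
        # they do, the weighted mean falls back on the summed coverage
        denom <- max(L, covered)
        val <- (sum(grp$cn * grp$ov) + 2 * max(0, L - covered)) / denom
        cn[q, grp$sample[[1L]]] <- val
      }
    }
  }
  structure(list(cn = cn, cnvrs = cnvrs, samples = samples),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d autosomal CNVRs x %d samples (%d populations)\n",
              nrow(x$cn), ncol(x$cn),
              length(unique(x$samples$population_id))))
  invisible(x)
}

#' The Vst population-differentiation statistic
#'
#' `Vst = (Vt - Vs) / Vt`, where `Vt` is the total variance of copy
#' numbers in the pooled two-population sample and `Vs` is the mean
#' within-population variance weighted by population size:
#' `Vs = (nA * VA + nB * VB) / (nA + nB)`. All variances use the
#' population estimator (denominator n). The result is clamped to
#' `[0, 1]`; when `Vt = 0` (all samples identical) Vst is defined as 0.
#'
#' @param cn_a,cn_b numeric copy-number vectors for the two populations
#'   (each of length >= 2).
#' @return named numeric `c(v_t, v_s, vst)`.
#' @examples
#' vst(c(2, 2, 4, 4), c(2, 2, 2, 2))["vst"]  # 1/3
#' @export
vst <- function(cn_a, cn_b) {
  n_a <- length(cn_a); n_b <- length(cn_b)
  if (n_a < 2L || n_b < 2L)
    .stopf("vst requires at least 2 samples per population (got %d, %d)",
           n_a, n_b)
  v_t <- .popvar(c(cn_a, cn_b))
  v_s <- (n_a * .popvar(cn_a) + n_b * .popvar(cn_b)) / (n_a + n_b)
  v <- if (v_t > 0) (v_t - v_s) / v_t else 0
  c(v_t = v_t, v_s = v_s, vst = min(1, max(0, v)))
}

#' Pairwise Vst for every autosomal CNVR
#'
#' @param mat a `cn_matrix` (see [build_cn_matrix()]).
#' @param pop_a,pop_b population ids present in the matrix, each with at
#'   least 2 samples.
#' @return data.frame with one row per CNVR in genome order: `cnvr_id`,
#'   `chrom`, `start`, `end`, `pop_a`, `pop_b`, `n_a`, `n_b`, `v_t`,
#'   `v_s`, `vst`, `selected` (initialised `FALSE`; see
#'   [select_differentiated()]).
#' @export
pairwise_vst <- function(mat, pop_a, pop_b) {
  pops <- mat$samples$population_id
  if (!pop_a %in% pops || !pop_b %in% pops)
    .stopf("population(s) not in matrix: %s",
           paste(setdiff(c(pop_a, pop_b), pops), collapse = ", "))
  a_cols <- mat$samples$sample_id[pops == pop_a]
  b_cols <- mat$samples$sample_id[pops == pop_b]
  if (length(a_cols) < 2L || length(b_cols) < 2L)
    .stopf("both populations need >= 2 samples for Vst (%s: %d, %s: %d)",
           pop_a, length(a_cols), pop_b, length(b_cols))
  stats <- t(vapply(seq_len(nrow(mat$cn)), function(i)
    vst(mat$cn[i, a_cols], mat$cn[i, b_cols]), numeric(3)))
  out <- data.frame(
    cnvr_id = mat$cnvrs$cnvr_id, chrom = mat$cnvrs$chrom,
    start = mat$cnvrs$start, end = mat$cnvrs$end,
    pop_a = pop_a, pop_b = pop_b,
    n_a = length(a_cols), n_b = length(b_cols),
    v_t = stats[, "v_t"], v_s = stats[, "v_s"], vst = stats[, "vst"],
    selected = FALSE, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Empirical top-fraction threshold (nearest rank)
#'
#' `k = ceiling(top_fraction * n)`; the threshold is the k-th largest
#' value. Records with `vst >= threshold` are selected, so ties at the
#' threshold may push the selected count above `k`.
#'
#' @param values finite numeric vector (n >= 1).
#' @param top_fraction upper-tail fraction (default 0.01, the top 1%).
#' @return list with `threshold`, `k`, `n`.
#' @export
empirical_threshold <- function(values, top_fraction = 0.01) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) .stopf("empirical_threshold: no finite values")
  k <- ceiling(top_fraction * n)
  list(threshold = sort(values, decreasing = TRUE)[[k]], k = k, n = n)
}

#' Flag putative population-differentiated CNVRs
#'
#' Sets the `selected` flag on every record whose Vst reaches the
#' threshold. When `threshold` is omitted it is computed from the records'
#' own empirical distribution via [empirical_threshold()] (computed
#' separately for each population pair, as the per-pair empirical
#' distributions differ).
#'
#' @param records a [pairwise_vst()] table for one population pair.
#' @param threshold numeric threshold, or `NULL` to use the empirical
#'   top-`top_fraction` value.
#' @param top_fraction passed to [empirical_threshold()] when `threshold`
#'   is `NULL`.
#' @return the records with `selected` set; the threshold used is attached
#'   as `attr(x, "threshold")` (list with `threshold`, `k`, `n`).
#' @export
select_differentiated <- function(records, threshold = NULL,
                                  top_fraction = 0.01) {
  thr <- if (is.null(threshold))
    empirical_threshold(records$vst, top_fraction)
  else list(threshold = threshold, k = NA_integer_, n = nrow(records))
  records$selected <- records$vst >= thr$threshold
  attr(records, "threshold") <- thr
  records
}

#' Genes selected in every one of several pairwise comparisons
#'
#' @param gene_sets named list of character vectors, one per population
#'   pair (e.g. genes overlapping the selected CNVRs of that pair).
#' @return list with `common` (genes present in all sets) and `provenance`
#'   (data.frame gene x pair membership).
#' @export
intersect_comparisons <- function(gene_sets) {
  if (length(gene_sets) == 0L)
    return(list(common = character(0),
                provenance = data.frame(gene = character())))
  common <- Reduce(intersect, gene_sets)
  all_genes <- sort(unique(unlist(gene_sets)))
  prov <- data.frame(gene = all_genes, stringsAsFactors = FALSE)
  for (p in names(gene_sets)) prov[[p]] <- all_genes %in% gene_sets[[p]]
  list(common = sort(common), provenance = prov)
}
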