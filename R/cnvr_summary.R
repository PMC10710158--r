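#' Summarize a CNVR set
#'
#' Counts by Dup/Del/Mixed class, median and total CNVR length, and the
#' fraction of the genome covered (total CNVR length divided by total
#' genome length). Two counting units are reported: per-CNVR class counts
#' (`n_dup` + `n_del` + `n_mixed` = `n_cnvr`) and per-member call type
#' counts (`n_member_dup`, `n_member_del`), since cohort-level tables in
#' the field often mix the two units.
#'
#' @param cnvrs a `cnvr_set` or a CNVR data.frame with `start`, `end`,
#'   `cnvr_type` (and optionally `n_members`).
#' @param genome a [genome_def].
#' @return one-row data.frame: `n_cnvr`, `n_dup`, `n_del`, `n_mixed`,
#'   `pct_mixed`, `n_member_dup`, `n_member_del`, `median_length`,
#'   `total_length`, `coverage_fraction`.
#' @export
summarize_cnvrs <- function(cnvrs, genome) {
  members <- NULL
  if (inherits(cnvrs, "cnvr_set")) {
    members <- cnvrs$members
    cnvrs <- cnvrs$cnvrs
  }
  if (nrow(cnvrs) == 0L) {
    return(data.frame(n_cnvr = 0L, n_dup = 0L, n_del = 0L, n_mixed = 0L,
                      pct_mixed = 0, n_member_dup = 0L, n_member_del = 0L,
                      median_length = 0, total_length = 0,
                      coverage_fraction = 0))
  }
  len <- cnvrs$end - cnvrs$start
  n <- nrow(cnvrs)
  n_mixed <- sum(cnvrs$cnvr_type == "MIXED")
  data.frame(
    n_cnvr = n,
    n_dup = sum(cnvrs$cnvr_type == "DUP"),
    n_del = sum(cnvrs$cnvr_type == "DEL"),
    n_mixed = n_mixed,
    pct_mixed = 100 * n_mixed / n,
    n_member_dup = if (is.null(members)) NA_integer_
                   else sum(members$cnv_type == "DUP"),
    n_member_del = if (is.null(members)) NA_integer_
                   else sum(members$cnv_type == "DEL"),
    median_length = stats::median(len),
    total_length = sum(len),
    coverage_fraction = sum(len) / genome_length(genome)
  )
}

#' Per-breed CNVR summary table
#'
#' One summary row per breed plus sample counts, mirroring the usual
#' per-breed CNVR statistics table (breed, n samples, CNVR count, class
#' counts, median/total length, genome coverage).
#'
#' @param breed_sets named list of breed `cnvr_set` objects.
#' @param samples sample sheet data.frame (`sample_id`, `population_id`).
#' @param genome a [genome_def].
#' @return data.frame with one row per breed.
#' @export
cnvr_summary_table <- function(breed_sets, samples, genome) {
  rows <- lapply(names(breed_sets), function(b) {
    s <- summarize_cnvrs(breed_sets[[b]], genome)
    cbind(data.frame(breed = b,
                     n_samples = sum(samples$population_id == b)), s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default CNVR length histogram bin edges (bp)
#'
#' 1-2-4-6-8-10 kb, then 10 kb steps of 10 kb up to 100 kb, then 100 kb
#' steps up to 400 kb; lengths above the last edge fall in an open top bin.
#' @return numeric vector of strictly increasing edges.
#' @export
default_length_bins <- function() {
  c(1, 2, 4, 6, 8, seq(10, 100, by = 10), seq(200, 400, by = 100)) * 1000
}

#' CNVR length distribution by class
#'
#' Bins CNVR lengths into `[edge_i, edge_{i+1})` intervals with an open top
#' bin above the last edge, stacked by Dup/Del/Mixed class. Lengths below
#' the first edge are counted in a flagged underflow bin.
#'
#' @param cnvrs a `cnvr_set` or CNVR data.frame.
#' @param bin_edges strictly increasing bp edges
#'   (default [default_length_bins()]).
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`,
#'   `n_dup`, `n_del`, `n_mixed`, `n_total`, `fraction`, `underflow`.
#'   Fractions sum to 1 over all bins when any CNVR is present.
#' @export
length_histogram <- function(cnvrs, bin_edges = default_length_bins()) {
  if (inherits(cnvrs, "cnvr_set")) cnvrs <- cnvrs$cnvrs
  if (is.unsorted(bin_edges, strictly = TRUE))
    .stopf("bin edges must be strictly increasing")
  lower <- c(0, bin_edges)
  upper <- c(bin_edges, Inf)
  labels <- c("underflow",
              sprintf("[%g,%g)", bin_edges[-length(bin_edges)],
                      bin_edges[-1L]),
              sprintf(">=%g", bin_edges[[length(bin_edges)]]))
  out <- data.frame(bin = labels, lower = lower, upper = upper,
                    n_dup = 0L, n_del = 0L, n_mixed = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(cnvrs) > 0L) {
    len <- cnvrs$end - cnvrs$start
    bin_idx <- findInterval(len, lower)  # 1 = underflow
    for (cls in c("DUP", "DEL", "MIXED")) {
      tab <- table(factor(bin_idx[cnvrs$cnvr_type == cls],
                          levels = seq_along(labels)))
      out[[paste0("n_", tolower(sub("MIXED", "mixed", cls)))]] <-
        as.integer(tab)
    }
  }
  out$n_total <- out$n_dup + out$n_del + out$n_mixed
  total <- sum(out$n_total)
  out$fraction <- if (total > 0) out$n_total / total else 0
  out$underflow <- out$bin == "underflow"
  if (any(out$n_total > 0 & out$underflow))
    .warnf("%d CNVR(s) shorter than the first bin edge counted as underflow",
           out$n_total[out$underflow])
  out
}
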