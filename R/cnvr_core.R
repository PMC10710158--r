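#' Filter CNV calls by length and chromosome placement
#'
#' Keeps a call iff its length (`end - start`) is at least `min_length`
#' (so exactly 1,000 bp passes the default 1 kb cut: the filter removes
#' lengths strictly less than the minimum) and its chromosome is in the
#' genome's placed set (calls on unplaced scaffolds are removed).
#'
#' @param calls a `cnv_calls` table.
#' @param genome a [genome_def].
#' @param min_length minimum call length in bp (default 1000).
#' @return list with `calls` (kept rows) and `drop_report` (data.frame of
#'   counts by reason: `short`, `unplaced`).
#' @export
filter_calls <- function(calls, genome, min_length = 1000) {
  len <- calls$end - calls$start
  short <- len < min_length
  unplaced <- !calls$chrom %in% genome$placed_set
  keep <- !short & !unplaced
  report <- data.frame(
    reason = c("short", "unplaced"),
    n_dropped = c(sum(short), sum(unplaced & !short)),
    stringsAsFactors = FALSE
  )
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, drop_report = report)
}

#' Reciprocal overlap fractions of two intervals
#'
#' For intervals on the same chromosome, returns the overlap length divided
#' by each interval's own length. Two intervals satisfy the k% reciprocal
#' overlap criterion when both fractions are at least k/100.
#'
#' @param a,b numeric length-2 vectors `c(start, end)` (half-open) or
#'   single-row interval data.frames with `chrom`, `start`, `end`.
#' @return numeric `c(frac_a, frac_b)`, zero when disjoint.
#' @examples
#' reciprocal_overlap(c(100, 200), c(150, 260))  # 0.5, 0.4545...
#' @export
reciprocal_overlap <- function(a, b) {
  get <- function(x) {
    if (is.data.frame(x)) {
      list(chrom = x$chrom[[1L]], start = x$start[[1L]], end = x$end[[1L]])
    } else {
      list(chrom = NA_character_, start = x[[1L]], end = x[[2L]])
    }
  }
  ia <- get(a); ib <- get(b)
  if (!is.na(ia$chrom) && !is.na(ib$chrom) && ia$chrom != ib$chrom)
    .stopf("reciprocal_overlap: intervals on different chromosomes")
  ov <- .ov_len(ia$start, ia$end, ib$start, ib$end)
  c(frac_a = ov / (ia$end - ia$start), frac_b = ov / (ib$end - ib$start))
}

# candidate overlapping pairs within one interval table, as a 2-column index
# matrix restricted to pairs meeting the reciprocal-overlap threshold
.reciprocal_edges <- function(df, frac) {
  if (nrow(df) < 2L) return(matrix(integer(), ncol = 2L))
  hits <- GenomicRanges::findOverlaps(.as_granges(df),
                                      drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  same <- df$chrom[i] == df$chrom[j]
  i <- i[same]; j <- j[same]
  if (length(i) == 0L) return(matrix(integer(), ncol = 2L))
  ov <- .ov_len(df$start[i], df$end[i], df$start[j], df$end[j])
  ok <- ov / (df$end[i] - df$start[i]) >= frac &
        ov / (df$end[j] - df$start[j]) >= frac
  cbind(i[ok], j[ok])
}

#' Within-population recurrence filter
#'
#' Keeps a call iff at least `min_individuals` distinct samples of its
#' population (the call's own sample counts as one) carry a call of any CNV
#' type matching it at `match_frac` reciprocal overlap. Kept-status is
#' computed on the full call set before any removal, so the filter is
#' symmetric and order-independent. Populations represented by fewer than
#' `min_individuals` samples cannot satisfy the criterion; their calls are
#' dropped with a warning.
#'
#' @param calls filtered `cnv_calls` (see [filter_calls()]).
#' @param min_individuals minimum number of distinct carriers (default 2).
#' @param match_frac reciprocal-overlap fraction defining a match
#'   (default 0.5).
#' @return the kept calls (same columns, original order preserved).
#' @export
recurrence_filter <- function(calls, min_individuals = 2, match_frac = 0.5) {
  if (nrow(calls) == 0L) return(calls)
  keep <- logical(nrow(calls))
  for (pop in unique(calls$population_id)) {
    p_idx <- which(calls$population_id == pop)
    n_samples <- length(unique(calls$sample_id[p_idx]))
    if (n_samples < min_individuals) {
      .warnf("population %s has %d sample(s) with calls; all its calls fail the %d-individual recurrence criterion",
             pop, n_samples, min_individuals)
      next
    }
    for (chr in unique(calls$chrom[p_idx])) {
      idx <- p_idx[calls$chrom[p_idx] == chr]
      sub <- calls[idx, , drop = FALSE]
      edges <- .reciprocal_edges(sub, match_frac)
      # carriers per call: own sample plus samples of reciprocal matches
      carriers <- lapply(seq_len(nrow(sub)), function(i) sub$sample_id[[i]])
      if (nrow(edges) > 0L) {
        for (k in seq_len(nrow(edges))) {
          i <- edges[k, 1L]; j <- edges[k, 2L]
          carriers[[i]] <- c(carriers[[i]], sub$sample_id[[j]])
          carriers[[j]] <- c(carriers[[j]], sub$sample_id[[i]])
        }
      }
      n_carriers <- vapply(carriers, function(s) length(unique(s)),
                           integer(1))
      keep[idx] <- n_carriers >= min_individuals
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a CNVR from its member CNV types
#'
#' All members duplications: `DUP`; all deletions: `DEL`; both types
#' present: `MIXED`. Order-invariant, and `MIXED` is absorbing under member
#' union.
#'
#' @param types character vector of member `cnv_type` values
#'   (`"DUP"`/`"DEL"`).
#' @return one of `"DUP"`, `"DEL"`, `"MIXED"`.
#' @export
classify_cnvr <- function(types) {
  if (length(types) == 0L) .stopf("classify_cnvr: no members")
  has_dup <- any(types == "DUP")
  has_del <- any(types == "DEL")
  if (has_dup && has_del) "MIXED" else if (has_dup) "DUP" else "DEL"
}

# assemble a cnvr_set from member calls + component labels
.build_cnvr_set <- function(members, comp, level, genome) {
  if (nrow(members) == 0L) {
    cnvrs <- data.frame(cnvr_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        level = character(), cnvr_type = character(),
                        n_members = integer(), n_breeds = integer(),
                        breeds = character(), stringsAsFactors = FALSE)
    members$cnvr_id <- character(0)
    return(structure(list(cnvrs = cnvrs, members = members),
                     class = "cnvr_set"))
  }
  sp <- split(seq_len(nrow(members)), comp)
  cnvrs <- do.call(rbind, lapply(sp, function(idx) {
    m <- members[idx, , drop = FALSE]
    breeds <- sort(unique(m$population_id))
    data.frame(
      chrom = m$chrom[[1L]], start = min(m$start), end = max(m$end),
      level = level, cnvr_type = classify_cnvr(m$cnv_type),
      n_members = nrow(m), n_breeds = length(breeds),
      breeds = paste(breeds, collapse = ","), stringsAsFactors = FALSE
    )
  }))
  ord <- order(.chrom_rank(cnvrs$chrom, genome), cnvrs$start, cnvrs$end)
  cnvrs <- cnvrs[ord, , drop = FALSE]
  # deterministic ids: {level}_{chrom}_{1-based rank within chromosome}
  rank_in_chrom <- stats::ave(seq_len(nrow(cnvrs)), cnvrs$chrom,
                              FUN = seq_along)
  cnvrs$cnvr_id <- sprintf("%s_%s_%d", level, cnvrs$chrom, rank_in_chrom)
  cnvrs <- cnvrs[, c("cnvr_id", "chrom", "start", "end", "level",
                     "cnvr_type", "n_members", "n_breeds", "breeds")]
  rownames(cnvrs) <- NULL
  # map component label (1..k, = index into sp) -> cnvr_id through the sort
  id_by_comp <- character(length(sp))
  id_by_comp[ord] <- cnvrs$cnvr_id
  members$cnvr_id <- id_by_comp[comp]
  rownames(members) <- NULL
  structure(list(cnvrs = cnvrs, members = members), class = "cnvr_set")
}

#' Merge CNV calls into CNVRs by reciprocal overlap (single linkage)
#'
#' Builds the graph whose vertices are calls and whose edges join pairs with
#' at least `frac` reciprocal overlap on both sides; each connected
#' component becomes one CNVR whose span is the union of its member spans.
#' Chains are merged transitively (single linkage), so the result is a
#' partition of the input calls. Singleton components still form CNVRs
#' (their recurrence support came from [recurrence_filter()]). The output
#' is sorted by genome order and is invariant to input permutation.
#'
#' @param calls recurrence-filtered `cnv_calls` covering any number of
#'   chromosomes.
#' @param genome a [genome_def] (sort order and id scheme).
#' @param frac reciprocal-overlap threshold, closed (exactly `frac` merges);
#'   default 0.5.
#' @param level CNVR level label, `"BREED"` or `"COHORT"`.
#' @return a `cnvr_set`: list with `cnvrs` (one row per CNVR: `cnvr_id`,
#'   `chrom`, `start`, `end`, `level`, `cnvr_type`, `n_members`,
#'   `n_breeds`, `breeds`) and `members` (the input calls with their
#'   `cnvr_id`).
#' @export
merge_reciprocal <- function(calls, genome, frac = 0.5, level = "BREED") {
  calls <- as.data.frame(calls)[, .CALL_COLS, drop = FALSE]
  if (nrow(calls) == 0L)
    return(.build_cnvr_set(calls, integer(0), level, genome))
  # canonical order makes components independent of input permutation
  ord <- order(.chrom_rank(calls$chrom, genome), calls$start, calls$end,
               calls$sample_id, calls$copy_number)
  calls <- calls[ord, , drop = FALSE]
  comp <- integer(nrow(calls))
  offset <- 0L
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr)
    sub <- calls[idx, , drop = FALSE]
    edges <- .reciprocal_edges(sub, frac)
    labels <- .uf_components(nrow(sub), edges)
    comp[idx] <- labels + offset
    offset <- offset + max(labels)
  }
  .build_cnvr_set(calls, comp, level, genome)
}

#' Build per-breed CNVR sets from a cohort call table
#'
#' Applies [merge_reciprocal()] separately to each population's calls.
#'
#' @inheritParams merge_reciprocal
#' @return named list of `cnvr_set`, one per population.
#' @export
build_breed_cnvrs <- function(calls, genome, frac = 0.5) {
  pops <- sort(unique(calls$population_id))
  out <- lapply(pops, function(p)
    merge_reciprocal(calls[calls$population_id == p, , drop = FALSE],
                     genome, frac = frac, level = "BREED"))
  stats::setNames(out, pops)
}

#' Merge breed CNVR sets into cohort CNVRs
#'
#' Pools the breed-level CNVR intervals of all populations and re-applies
#' reciprocal-overlap single-linkage merging. Member-call provenance is
#' carried through: each cohort CNVR's members are the union of the member
#' calls of the breed CNVRs it absorbed, its breed set is recomputed from
#' them, and its Dup/Del/Mixed class is recomputed over all transitive
#' member calls. With a single breed set the operation is idempotent.
#'
#' @param breed_sets list of breed-level `cnvr_set` objects
#'   (see [build_breed_cnvrs()]).
#' @inheritParams merge_reciprocal
#' @return a cohort-level `cnvr_set`.
#' @export
merge_breed_to_cohort <- function(breed_sets, genome, frac = 0.5) {
  if (length(breed_sets) == 0L) .stopf("no breed CNVR sets supplied")
  pooled <- do.call(rbind, lapply(seq_along(breed_sets), function(k) {
    s <- breed_sets[[k]]$cnvrs
    if (nrow(s) == 0L) return(NULL)
    data.frame(set_idx = k, breed_cnvr_id = s$cnvr_id, chrom = s$chrom,
               start = s$start, end = s$end, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L)
    return(.build_cnvr_set(.empty_calls(), integer(0), "COHORT", genome))
  ord <- order(.chrom_rank(pooled$chrom, genome), pooled$start, pooled$end,
               pooled$set_idx, pooled$breed_cnvr_id)
  pooled <- pooled[ord, , drop = FALSE]
  comp <- integer(nrow(pooled))
  offset <- 0L
  for (chr in unique(pooled$chrom)) {
    idx <- which(pooled$chrom == chr)
    edges <- .reciprocal_edges(pooled[idx, , drop = FALSE], frac)
    labels <- .uf_components(length(idx), edges)
    comp[idx] <- labels + offset
    offset <- offset + max(labels)
  }
  # expand back to transitive member calls, tagged with their component
  members <- do.call(rbind, lapply(seq_len(nrow(pooled)), function(r) {
    s <- breed_sets[[pooled$set_idx[[r]]]]
    m <- s$members[s$members$cnvr_id == pooled$breed_cnvr_id[[r]], ,
                   drop = FALSE]
    m <- m[, .CALL_COLS, drop = FALSE]
    m$.comp <- comp[[r]]
    m
  }))
  .build_cnvr_set(members[, .CALL_COLS, drop = FALSE], members$.comp,
                  "COHORT", genome)
}

#' Run the full call-to-cohort CNVR construction in memory
#'
#' Convenience wrapper chaining the documented stage order: length and
#' placement filters, within-population recurrence filter, per-breed
#' reciprocal-overlap merging, and breed-to-cohort merging.
#'
#' @inheritParams filter_calls
#' @inheritParams recurrence_filter
#' @param frac reciprocal-overlap threshold used for recurrence matching
#'   and both merge stages (default 0.5).
#' @return list with `cohort` (cohort `cnvr_set`), `breed_sets`,
#'   `drop_report`, `n_after_recurrence`.
#' @export
build_cohort_cnvrs <- function(calls, genome, min_length = 1000,
                               min_individuals = 2, frac = 0.5) {
  filt <- filter_calls(calls, genome, min_length = min_length)
  recurrent <- recurrence_filter(filt$calls,
                                 min_individuals = min_individuals,
                                 match_frac = frac)
  breed_sets <- build_breed_cnvrs(recurrent, genome, frac = frac)
  cohort <- if (length(breed_sets) > 0L)
    merge_breed_to_cohort(breed_sets, genome, frac = frac)
  else
    merge_reciprocal(recurrent, genome, frac = frac, level = "COHORT")
  list(cohort = cohort, breed_sets = breed_sets,
       drop_report = filt$drop_report,
       n_after_recurrence = nrow(recurrent))
}

#' @export
print.cnvr_set <- function(x, ...) {
  lvl <- if (nrow(x$cnvrs)) x$cnvrs$level[[1L]] else "?"
  cat(sprintf("cnvr_set (%s): %d CNVRs from %d member calls\n",
              lvl, nrow(x$cnvrs), nrow(x$members)))
  if (nrow(x$cnvrs))
    print(table(x$cnvrs$cnvr_type))
  invisible(x)
}
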