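#' Read per-sample CNV calls in CNVnator text call format
#'
#' Parses the whitespace-delimited call output of the read-depth caller
#' CNVnator: `type  chrom:start-end  size  normalized_RD  [e-values, q0 ...]`.
#' The normalized read depth is converted to an estimated copy number as
#' `copy_number = 2 * normalized_RD` (diploid baseline). The printed
#' `chrom:start-end` region is interpreted as 1-based-start half-open, so the
#' stored call length is `end - start`. The type is resolved from the copy
#' number (`CN < 2` deletion, `CN > 2` duplication); a line whose copy number
#' is exactly 2 carries no variant signal and becomes an error record, as
#' does any line whose region string cannot be parsed. Trailing quality
#' columns are preserved verbatim in `source_line` but no quality filter is
#' applied.
#'
#' @param path path to a CNVnator call file (one sample).
#' @param sample_id sample identifier recorded on every call.
#' @param population_id population/breed identifier recorded on every call.
#' @return a `cnv_calls` data.frame (columns `sample_id`, `population_id`,
#'   `chrom`, `start`, `end`, `cnv_type`, `copy_number`, `source_line`) with
#'   the line-level error report available via [call_errors()].
#' @export
read_cnvnator_calls <- function(path, sample_id, population_id) {
  if (!file.exists(path)) .stopf("CNVnator call file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(.new_call_set(.empty_calls(), .empty_call_errors()))

  fields <- strsplit(trimws(lines), "[ \t]+")
  err <- function(i, reason) data.frame(line_number = i, line = lines[i],
                                        reason = reason,
                                        stringsAsFactors = FALSE)
  calls <- vector("list", length(lines))
  errors <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 4L) { errors[[i]] <- err(i, "too_few_columns"); next }
    type_raw <- tolower(f[[1L]])
    if (!type_raw %in% c("deletion", "duplication")) {
      errors[[i]] <- err(i, "unknown_type"); next
    }
    m <- regmatches(f[[2L]],
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", f[[2L]]))[[1L]]
    if (length(m) != 4L) { errors[[i]] <- err(i, "bad_region"); next }
    start <- as.numeric(m[[3L]]); end <- as.numeric(m[[4L]])
    if (end <= start) { errors[[i]] <- err(i, "empty_interval"); next }
    rd <- suppressWarnings(as.numeric(f[[4L]]))
    if (!is.finite(rd) || rd < 0) {
      errors[[i]] <- err(i, "bad_read_depth"); next
    }
    cn <- 2 * rd
    cnv_type <- .type_from_cn(cn)
    if (is.na(cnv_type)) { errors[[i]] <- err(i, "neutral_copy_number"); next }
    calls[[i]] <- data.frame(
      sample_id = sample_id, population_id = population_id,
      chrom = m[[2L]], start = start, end = end,
      cnv_type = cnv_type, copy_number = cn, source_line = lines[i],
      stringsAsFactors = FALSE
    )
  }
  .new_call_set(
    do.call(rbind, c(list(.empty_calls()), Filter(Negate(is.null), calls))),
    do.call(rbind, c(list(.empty_call_errors()),
                     Filter(Negate(is.null), errors)))
  )
}

#' Read per-sample CNV calls from a BED-like table
#'
#' Expects at least five tab- or space-separated columns: `chrom`, `start`
#' (0-based), `end`, `type` (`DEL`/`DUP`, or `deletion`/`duplication`), and
#' `copy_number`. Coordinates are shifted to the internal 1-based-start
#' half-open convention by `start + 1` (the end column is shared between the
#' two conventions here, so stored length stays `end - start`). A header
#' line is detected by a non-numeric start column and skipped. Validation
#' matches [read_cnvnator_calls()]: types are re-derived from the copy
#' number and degenerate intervals become error records.
#'
#' @inheritParams read_cnvnator_calls
#' @return a `cnv_calls` data.frame; see [read_cnvnator_calls()].
#' @export
read_bed_calls <- function(path, sample_id, population_id) {
  if (!file.exists(path)) .stopf("BED call file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) > 0L) {
    first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
    if (length(first) >= 2L &&
        is.na(suppressWarnings(as.numeric(first[[2L]]))))
      lines <- lines[-1L]
  }
  if (length(lines) == 0L)
    return(.new_call_set(.empty_calls(), .empty_call_errors()))

  fields <- strsplit(trimws(lines), "[ \t]+")
  n_min <- min(lengths(fields))
  if (n_min < 5L)
    .stopf("BED call file %s is missing required columns %s",
           path, paste(c("chrom", "start", "end", "type",
                         "copy_number")[seq(n_min + 1L, 5L)],
                       collapse = ", "))
  err <- function(i, reason) data.frame(line_number = i, line = lines[i],
                                        reason = reason,
                                        stringsAsFactors = FALSE)
  calls <- vector("list", length(lines))
  errors <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    bed_start <- suppressWarnings(as.numeric(f[[2L]]))
    bed_end <- suppressWarnings(as.numeric(f[[3L]]))
    cn <- suppressWarnings(as.numeric(f[[5L]]))
    if (!is.finite(bed_start) || !is.finite(bed_end)) {
      errors[[i]] <- err(i, "bad_coordinates"); next
    }
    if (bed_end <= bed_start) { errors[[i]] <- err(i, "empty_interval"); next }
    if (!is.finite(cn) || cn < 0) {
      errors[[i]] <- err(i, "bad_copy_number"); next
    }
    cnv_type <- .type_from_cn(cn)
    if (is.na(cnv_type)) { errors[[i]] <- err(i, "neutral_copy_number"); next }
    calls[[i]] <- data.frame(
      sample_id = sample_id, population_id = population_id,
      chrom = f[[1L]], start = bed_start + 1, end = bed_end,
      cnv_type = cnv_type, copy_number = cn, source_line = lines[i],
      stringsAsFactors = FALSE
    )
  }
  .new_call_set(
    do.call(rbind, c(list(.empty_calls()), Filter(Negate(is.null), calls))),
    do.call(rbind, c(list(.empty_call_errors()),
                     Filter(Negate(is.null), errors)))
  )
}

#' Read a labeled interval table (QTL traits or published CNVR sets)
#'
#' Tab-separated columns `label`, `chrom`, `start`, `end` with 1-based
#' inclusive input coordinates, converted internally to half-open by
#' `end + 1` (so an inclusive row 100-199 becomes [100, 200), length 100).
#' Rows on chromosomes absent from the genome definition are skipped with a
#' warning; the skip count is available as `attr(x, "n_skipped")`.
#'
#' @param path path to the TSV (an optional header line is detected and
#'   skipped).
#' @param genome a [genome_def] used to validate chromosomes.
#' @param kind label kind, `"QTL"` or `"PUBLISHED_CNVR"` (recorded on the
#'   result).
#' @return data.frame with columns `label`, `chrom`, `start`, `end` (internal
#'   convention) and attributes `kind`, `n_skipped`.
#' @export
read_interval_table <- function(path, genome,
                                kind = c("QTL", "PUBLISHED_CNVR")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .stopf("interval table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  empty <- data.frame(label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) > 0L) {
    first <- strsplit(lines[[1L]], "\t")[[1L]]
    if (length(first) >= 3L &&
        is.na(suppressWarnings(as.numeric(first[[3L]]))))
      lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    attr(empty, "kind") <- kind; attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  fields <- strsplit(lines, "\t")
  if (min(lengths(fields)) < 4L)
    .stopf("interval table %s needs 4 tab-separated columns", path)
  tab <- data.frame(
    label = vapply(fields, `[[`, "", 1L),
    chrom = vapply(fields, `[[`, "", 2L),
    start = as.numeric(vapply(fields, `[[`, "", 3L)),
    end = as.numeric(vapply(fields, `[[`, "", 4L)) + 1,
    stringsAsFactors = FALSE
  )
  known <- tab$chrom %in% genome$chrom_names
  if (any(!known))
    .warnf("%d interval(s) on chromosomes absent from the genome skipped",
           sum(!known))
  out <- .sort_intervals(tab[known, , drop = FALSE], genome)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "n_skipped") <- sum(!known)
  out
}

#' Read a sample sheet
#'
#' TSV with header columns `sample_id`, `population_id` and optionally
#' `path` (per-sample call file) and `format` (`cnvnator` or `bed`).
#'
#' @param path sample sheet path.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .stopf("sample sheet not found: %s", path)
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "population_id")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    .stopf("sample sheet lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    .stopf("duplicated sample_id in sample sheet")
  if (!is.null(sheet$path)) {
    # relative call-file paths are resolved against the sheet's directory
    rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
    sheet$path[rel] <- file.path(dirname(normalizePath(path)),
                                 sheet$path[rel])
  }
  sheet
}

#' Write CNVRs to a BED-like file
#'
#' Emits 0-based-start half-open coordinates (internal start − 1; end
#' unchanged), with `name` = CNVR id, `score` = member count, then `type`
#' and the comma-separated contributing breed list. Rows are sorted by
#' genome chromosome order and start. The coordinate math round-trips
#' through [read_bed_calls()].
#'
#' @param cnvrs a `cnvr_set` (see [merge_reciprocal()]) or a CNVR
#'   data.frame.
#' @param path output path.
#' @param genome optional [genome_def] fixing the chromosome sort order.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path, genome = NULL) {
  df <- if (inherits(cnvrs, "cnvr_set")) cnvrs$cnvrs else cnvrs
  header <- "#chrom\tstart\tend\tname\tscore\ttype\tbreeds"
  if (nrow(df) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  df <- .sort_intervals(df, genome)
  out <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                 df$chrom, as.integer(df$start - 1), as.integer(df$end),
                 df$cnvr_id, df$n_members, df$cnvr_type, df$breeds)
  writeLines(c(header, out), path)
  invisible(path)
}
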