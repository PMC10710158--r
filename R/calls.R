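# The per-sample CNV call table: one row per call, internal 1-based
# half-open coordinates. Readers attach an "errors" attribute holding the
# line-level error report so that nothing is silently dropped:
# nrow(calls) + nrow(call_errors(calls)) == number of input records.

.CALL_COLS <- c("sample_id", "population_id", "chrom", "start", "end",
                "cnv_type", "copy_number", "source_line")

.empty_calls <- function() {
  data.frame(sample_id = character(), population_id = character(),
             chrom = character(), start = numeric(), end = numeric(),
             cnv_type = character(), copy_number = numeric(),
             source_line = character(), stringsAsFactors = FALSE)
}

.empty_call_errors <- function() {
  data.frame(line_number = integer(), line = character(),
             reason = character(), stringsAsFactors = FALSE)
}

.new_call_set <- function(calls, errors) {
  rownames(calls) <- NULL
  attr(calls, "errors") <- errors
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

#' Line-level error report of a reader
#'
#' Readers never silently drop malformed records; rejected lines are kept in
#' an error report attached to the returned call table.
#'
#' @param calls a call table returned by [read_cnvnator_calls()] or
#'   [read_bed_calls()].
#' @return data.frame with columns `line_number`, `line`, `reason`.
#' @export
call_errors <- function(calls) {
  e <- attr(calls, "errors")
  if (is.null(e)) .empty_call_errors() else e
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("cnv_calls: %d calls, %d samples, %d error records\n",
              nrow(x), length(unique(x$sample_id)), nrow(call_errors(x))))
  NextMethod()
}

# Resolve the CNV type from the copy number (diploid baseline 2). The copy
# number drives Vst, so it is authoritative over the caller's type label:
# CN < 2 -> DEL, CN > 2 -> DUP, CN == 2 -> rejected (no variant signal).
.type_from_cn <- function(cn) ifelse(cn < 2, "DEL", ifelse(cn > 2, "DUP", NA))

#' Combine call tables from several samples into one cohort table
#'
#' @param ... call tables (or a single list of them).
#' @return one `cnv_calls` table; error reports are concatenated.
#' @export
bind_calls <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is.data.frame(parts[[1L]])) parts <- parts[[1L]]
  if (length(parts) == 0L) return(.new_call_set(.empty_calls(),
                                               .empty_call_errors()))
  errs <- do.call(rbind, lapply(parts, call_errors))
  calls <- do.call(rbind, lapply(parts, function(p) {
    as.data.frame(p)[, .CALL_COLS, drop = FALSE]
  }))
  .new_call_set(calls, errs)
}
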