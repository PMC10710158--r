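# Internal helpers shared across modules. All genomic intervals in this
# package are 1-based-start, half-open [start, end); length = end - start.

# overlap length of [s1,e1) and [s2,e2); vectorised, 0 when disjoint
.ov_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# population variance (denominator n), the estimator used throughout Vst
.popvar <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- sum(x) / n
  sum((x - m)^2) / n
}

# rank of chromosomes in genome order; unknown chromosomes sort last
.chrom_rank <- function(chrom, genome) {
  r <- match(chrom, genome$chrom_names)
  r[is.na(r)] <- length(genome$chrom_names) + 1L
  r
}

# stable sort of an interval data.frame by (genome chromosome order, start, end)
.sort_intervals <- function(df, genome = NULL) {
  key <- if (is.null(genome)) df$chrom else .chrom_rank(df$chrom, genome)
  df[order(key, df$start, df$end), , drop = FALSE]
}

# Union-find with path compression; `edges` is a 2-column integer matrix of
# 1-based node indices. Returns component labels 1..k in order of first
# appearance, so the result is deterministic for a fixed node order.
.uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1L])
      rb <- find(edges[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# GRanges from an internal half-open interval table (GRanges is 1-based
# closed, so closed end = internal end - 1)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end - 1L)
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
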