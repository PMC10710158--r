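# Fixture builders and independent oracles shared across the test files.
# All fixtures are built in code; no binary data.

toy_genome <- function() {
  genome_def(c("chr1", "chr2", "chrX", "chrUn_scaf1"),
             c(1e6, 1e6, 5e5, 1e5))
}

# quick call-table builder; intervals half-open [start, end)
mk_calls <- function(chrom, start, end, sample = "s1", pop = "popA",
                     type = NULL, cn = NULL) {
  n <- max(length(chrom), length(start), length(end), length(sample))
  if (is.null(cn)) cn <- ifelse(rep_len(type %||% "DEL", n) == "DEL", 1, 3)
  if (is.null(type)) type <- ifelse(cn < 2, "DEL", "DUP")
  data.frame(
    sample_id = rep_len(sample, n), population_id = rep_len(pop, n),
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    end = rep_len(end, n), cnv_type = rep_len(type, n),
    copy_number = rep_len(cn, n), source_line = "test",
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- independent oracles -------------------------------------------------

# O(n^2) reciprocal-overlap edge matrix + flood-fill connected components;
# shares no code with the union-find / findOverlaps implementation path
brute_force_components <- function(calls, frac = 0.5) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || calls$chrom[i] != calls$chrom[j]) next
    ov <- max(0, min(calls$end[i], calls$end[j]) -
                 max(calls$start[i], calls$start[j]))
    adj[i, j] <- ov / (calls$end[i] - calls$start[i]) >= frac &&
                 ov / (calls$end[j] - calls$start[j]) >= frac
  }
  comp <- rep(NA_integer_, n)
  label <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    label <- label + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- label
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      frontier <- setdiff(nxt, which(!is.na(comp)))
    }
  }
  comp
}

# canonical signature of a CNVR partition: sorted member sets per span
partition_signature <- function(cnvr_set) {
  m <- cnvr_set$members
  sig <- lapply(split(m, m$cnvr_id), function(g)
    sort(paste(g$sample_id, g$chrom, g$start, g$end, sep = ":")))
  unname(sig[order(vapply(sig, `[[`, "", 1L))])
}

signature_from_labels <- function(calls, comp) {
  sig <- lapply(split(seq_len(nrow(calls)), comp), function(idx)
    sort(paste(calls$sample_id[idx], calls$chrom[idx], calls$start[idx],
               calls$end[idx], sep = ":")))
  unname(sig[order(vapply(sig, `[[`, "", 1L))])
}

# loop-based Vst, written from the definition with explicit accumulators
brute_force_vst <- function(a, b) {
  mean_loop <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }
  var_loop <- function(x) {
    m <- mean_loop(x); s <- 0
    for (v in x) s <- s + (v - m)^2
    s / length(x)
  }
  vt <- var_loop(c(a, b))
  vs <- (length(a) * var_loop(a) + length(b) * var_loop(b)) /
        (length(a) + length(b))
  if (vt == 0) 0 else min(1, max(0, (vt - vs) / vt))
}

# all-pairs interval intersection counting for overlap reports
brute_force_overlap_report <- function(cnvrs, intervals, min_bp = 1) {
  hits <- list()
  for (i in seq_len(nrow(cnvrs))) for (j in seq_len(nrow(intervals))) {
    if (cnvrs$chrom[i] != intervals$chrom[j]) next
    ov <- max(0, min(cnvrs$end[i], intervals$end[j]) -
                 max(cnvrs$start[i], intervals$start[j]))
    if (ov >= min_bp)
      hits[[length(hits) + 1L]] <- data.frame(
        cnvr_id = cnvrs$cnvr_id[i], label = intervals$label[j],
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(cnvr_id = character(), label = character()))
  unique(do.call(rbind, hits))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, max_len = 5e3) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  mk_calls(sample(chroms, n, replace = TRUE), start, start + len,
           sample = sprintf("s%d", sample.int(8, n, replace = TRUE)),
           cn = sample(c(0.5, 1, 3, 4), n, replace = TRUE))
}

# a two-gene GFF3 fixture: geneA (+, 2 exons with CDS and UTRs),
# geneB (-, single exon, non-coding); coordinates 1-based inclusive
write_gff3_fixture <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t5000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=txA1;Parent=geneA",
    "chr1\ttest\texon\t1000\t2000\t.\t+\t.\tID=exA1;Parent=txA1",
    "chr1\ttest\texon\t4000\t5000\t.\t+\t.\tID=exA2;Parent=txA1",
    "chr1\ttest\tCDS\t1500\t2000\t.\t+\t0\tID=cdsA1;Parent=txA1",
    "chr1\ttest\tCDS\t4000\t4500\t.\t+\t0\tID=cdsA2;Parent=txA1",
    "chr1\ttest\tgene\t20000\t21000\t.\t-\t.\tID=geneB",
    "chr1\ttest\ttranscript\t20000\t21000\t.\t-\t.\tID=txB1;Parent=geneB",
    "chr1\ttest\texon\t20000\t21000\t.\t-\t.\tID=exB1;Parent=txB1"
  ), ".gff3")
}

write_gtf_fixture <- function() {
  write_lines_tmp(c(
    paste0("chr1\ttest\tgene\t1000\t5000\t.\t+\t.\t",
           'gene_id "geneA";'),
    paste0("chr1\ttest\ttranscript\t1000\t5000\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA1";'),
    paste0("chr1\ttest\texon\t1000\t2000\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA1";'),
    paste0("chr1\ttest\texon\t4000\t5000\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA1";'),
    paste0("chr1\ttest\tCDS\t1500\t2000\t.\t+\t0\t",
           'gene_id "geneA"; transcript_id "txA1";'),
    paste0("chr1\ttest\tCDS\t4000\t4500\t.\t+\t0\t",
           'gene_id "geneA"; transcript_id "txA1";')
  ), ".gtf")
}
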