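#' Read gene models from GFF3 or GTF
#'
#' Imports gene annotation via [rtracklayer::import()] and normalizes both
#' dialects into one internal model used for positional CNVR annotation:
#' per gene the strand and gene-body span; per transcript the exon set,
#' coding span, UTR spans (taken from the file when present, otherwise
#' inferred as exonic sequence outside the coding span) and introns
#' (inter-exon gaps, whose boundaries are the splice sites). All
#' coordinates are converted to the internal 1-based-start half-open
#' convention.
#'
#' @param path path to a `.gff3`/`.gff` or `.gtf` file.
#' @return an object of class `gene_models`: a list of data.frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`), `transcripts`
#'   (`tx_id`, `gene_id`, `coding`), and per-feature tables `exons`, `cds`,
#'   `utr5`, `utr3`, `introns` keyed by `tx_id`/`gene_id`. Transcript
#'   records referencing a missing gene are reported in
#'   `attr(x, "errors")`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) .stopf("gene model file not found: %s", path)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
         else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0L) .stopf("no features parsed from %s", path)
  feat <- data.frame(
    type = tolower(as.character(gr$type)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr) + 1L,  # closed -> half-open
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (fmt == "gtf") {
    feat$gene_id <- as.character(gr$gene_id)
    feat$tx_id <- as.character(gr$transcript_id)
  } else {
    ids <- as.character(gr$ID)
    parents <- vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
    is_tx <- feat$type %in% c("mrna", "transcript")
    is_gene <- feat$type == "gene"
    feat$gene_id <- ifelse(is_gene, ids, NA_character_)
    feat$tx_id <- ifelse(is_tx, ids, NA_character_)
    feat$gene_id[is_tx] <- parents[is_tx]
    # children (exon/CDS/UTR) point at their transcript
    child <- !is_gene & !is_tx
    feat$tx_id[child] <- parents[child]
    tx2gene <- stats::setNames(feat$gene_id[is_tx], feat$tx_id[is_tx])
    feat$gene_id[child] <- unname(tx2gene[feat$tx_id[child]])
  }

  tx_types <- c("mrna", "transcript")
  sub_types <- c("exon", "cds", "five_prime_utr", "three_prime_utr",
                 "5utr", "3utr", "utr")
  tx_rows <- feat[feat$type %in% tx_types, , drop = FALSE]
  gene_rows <- feat[feat$type == "gene", , drop = FALSE]
  sub_rows <- feat[feat$type %in% sub_types, , drop = FALSE]
  sub_rows <- sub_rows[!is.na(sub_rows$tx_id), , drop = FALSE]

  # transcripts can be implicit in GTF files that only carry exon/CDS rows
  tx_tab <- unique(rbind(
    tx_rows[, c("tx_id", "gene_id"), drop = FALSE],
    sub_rows[, c("tx_id", "gene_id"), drop = FALSE]
  ))
  tx_tab <- tx_tab[!is.na(tx_tab$tx_id), , drop = FALSE]

  errors <- data.frame(id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  orphan <- is.na(tx_tab$gene_id)
  if (nrow(gene_rows) > 0L)
    orphan <- orphan | !tx_tab$gene_id %in% gene_rows$gene_id
  if (any(orphan)) {
    errors <- rbind(errors, data.frame(id = tx_tab$tx_id[orphan],
                                       reason = "transcript_without_gene",
                                       stringsAsFactors = FALSE))
    sub_rows <- sub_rows[!sub_rows$tx_id %in% tx_tab$tx_id[orphan], ,
                         drop = FALSE]
    tx_tab <- tx_tab[!orphan, , drop = FALSE]
  }

  keep <- c("tx_id", "gene_id", "chrom", "start", "end", "strand")
  exons <- sub_rows[sub_rows$type == "exon", keep, drop = FALSE]
  cds <- sub_rows[sub_rows$type == "cds", keep, drop = FALSE]
  utr5 <- sub_rows[sub_rows$type %in% c("five_prime_utr", "5utr"), keep,
                   drop = FALSE]
  utr3 <- sub_rows[sub_rows$type %in% c("three_prime_utr", "3utr"), keep,
                   drop = FALSE]

  # infer UTRs from exon-minus-coding-span where the file gives none
  if (nrow(utr5) == 0L && nrow(utr3) == 0L && nrow(cds) > 0L) {
    inferred <- .infer_utrs(exons, cds)
    utr5 <- inferred$utr5
    utr3 <- inferred$utr3
  }
  introns <- .derive_introns(exons)

  # gene table: explicit gene features, else span of the gene's exons
  if (nrow(gene_rows) > 0L) {
    genes <- unique(gene_rows[, c("gene_id", "chrom", "start", "end",
                                  "strand"), drop = FALSE])
  } else {
    sp <- split(exons, exons$gene_id)
    genes <- do.call(rbind, lapply(sp, function(e) data.frame(
      gene_id = e$gene_id[[1L]], chrom = e$chrom[[1L]],
      start = min(e$start), end = max(e$end), strand = e$strand[[1L]],
      stringsAsFactors = FALSE)))
  }
  if (is.null(genes) || nrow(genes) == 0L)
    .stopf("zero genes parsed from %s", path)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  tx_tab$coding <- tx_tab$tx_id %in% cds$tx_id
  out <- list(genes = genes, transcripts = tx_tab, exons = exons,
              cds = cds, utr5 = utr5, utr3 = utr3, introns = introns)
  attr(out, "errors") <- errors
  class(out) <- "gene_models"
  out
}

# introns = gaps between consecutive exons of one transcript; a transcript
# with k exons has k-1 introns and 2(k-1) splice boundaries
.derive_introns <- function(exons) {
  if (nrow(exons) == 0L)
    return(exons[0L, , drop = FALSE])
  sp <- split(exons, exons$tx_id)
  parts <- lapply(sp, function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(tx_id = e$tx_id[[1L]], gene_id = e$gene_id[[1L]],
               chrom = e$chrom[[1L]],
               start = e$end[-nrow(e)], end = e$start[-1L],
               strand = e$strand[[1L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(exons[0L, , drop = FALSE]),
                          Filter(Negate(is.null), parts)))
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# UTR = exonic sequence outside [min(CDS), max(CDS)); 5' vs 3' by strand
.infer_utrs <- function(exons, cds) {
  template <- exons[0L, , drop = FALSE]
  u5 <- list(); u3 <- list()
  for (tx in unique(cds$tx_id)) {
    e <- exons[exons$tx_id == tx, , drop = FALSE]
    if (nrow(e) == 0L) next
    cd <- cds[cds$tx_id == tx, , drop = FALSE]
    lo <- min(cd$start); hi <- max(cd$end)
    left <- e; left$end <- pmin(left$end, lo)
    left <- left[left$end > left$start, , drop = FALSE]
    right <- e; right$start <- pmax(right$start, hi)
    right <- right[right$end > right$start, , drop = FALSE]
    if (identical(e$strand[[1L]], "-")) {
      u5[[tx]] <- right; u3[[tx]] <- left
    } else {
      u5[[tx]] <- left; u3[[tx]] <- right
    }
  }
  list(utr5 = do.call(rbind, c(list(template), u5)),
       utr3 = do.call(rbind, c(list(template), u3)))
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}
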