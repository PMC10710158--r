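.CATEGORY_PRECEDENCE <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                          "upstream", "downstream", "intergenic")

# feature tables for one category, internal half-open coordinates
.splice_windows <- function(introns, splice_bp) {
  if (nrow(introns) == 0L) return(introns)
  left <- introns; left$end <- pmin(left$end, left$start + splice_bp)
  right <- introns; right$start <- pmax(right$start, right$end - splice_bp)
  out <- rbind(left, right)
  out[out$end > out$start, , drop = FALSE]
}

.flank_windows <- function(genes, width, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  if (nrow(genes) == 0L || width <= 0) return(genes[0L, , drop = FALSE])
  # "before" = genomically left of the gene: upstream on +, downstream on -
  before <- ifelse(genes$strand == "-", side == "downstream",
                   side == "upstream")
  out <- genes
  out$start <- ifelse(before, pmax(1, genes$start - width), genes$end)
  out$end <- ifelse(before, genes$start, genes$end + width)
  out[out$end > out$start, , drop = FALSE]
}

.any_hit <- function(df, feats) {
  if (is.null(feats) || nrow(feats) == 0L) return(logical(nrow(df)))
  hits <- GenomicRanges::findOverlaps(.as_granges(df), .as_granges(feats))
  seq_len(nrow(df)) %in% S4Vectors::queryHits(hits)
}

#' Positional annotation of CNVRs against gene models
#'
#' Assigns each CNVR exactly one category by fixed precedence over all
#' overlapped features of all transcripts: exonic > splicing > 5'UTR >
#' 3'UTR > intronic > upstream > downstream > intergenic. "Exonic" means
#' overlap with coding sequence (or any exon of a non-coding transcript);
#' "splicing" means overlap with the first/last `splice_bp` bases of an
#' intron; the upstream/downstream windows are strand-aware flanks of the
#' gene body. Independently of the category, `gene_ids` lists every gene
#' whose gene body overlaps the CNVR by at least 1 bp; for intergenic
#' CNVRs the nearest gene and its distance are reported.
#'
#' @param cnvrs a `cnvr_set` or CNVR data.frame (`cnvr_id`, `chrom`,
#'   `start`, `end`).
#' @param models a `gene_models` object from [read_gene_models()].
#' @param upstream_bp,downstream_bp flank window widths in bp
#'   (default 1000).
#' @param splice_bp splice-site window inside the intron, bp (default 2).
#' @return data.frame with one row per CNVR: `cnvr_id`, `chrom`, `start`,
#'   `end`, `category`, `gene_ids` (comma-separated, body overlap),
#'   `nearest_gene`, `distance_bp` (`NA` unless intergenic).
#' @export
annotate_context <- function(cnvrs, models, upstream_bp = 1000,
                             downstream_bp = 1000, splice_bp = 2) {
  df <- if (inherits(cnvrs, "cnvr_set")) cnvrs$cnvrs else cnvrs
  out <- data.frame(cnvr_id = df$cnvr_id, chrom = df$chrom,
                    start = df$start, end = df$end,
                    category = "intergenic", gene_ids = "",
                    nearest_gene = NA_character_, distance_bp = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(out)

  # exonic features: CDS of coding transcripts, whole exons of non-coding
  coding_tx <- models$transcripts$tx_id[models$transcripts$coding]
  exonic <- rbind(models$cds,
                  models$exons[!models$exons$tx_id %in% coding_tx, ,
                               drop = FALSE])
  cats <- list(
    exonic = exonic,
    splicing = .splice_windows(models$introns, splice_bp),
    UTR5 = models$utr5,
    UTR3 = models$utr3,
    intronic = models$introns,
    upstream = .flank_windows(models$genes, upstream_bp, "upstream"),
    downstream = .flank_windows(models$genes, downstream_bp, "downstream")
  )
  assigned <- rep(FALSE, nrow(df))
  for (cat in names(cats)) {
    hit <- .any_hit(df, cats[[cat]]) & !assigned
    out$category[hit] <- cat
    assigned <- assigned | hit
  }

  # gene-body overlaps, independent of category
  body_hits <- GenomicRanges::findOverlaps(.as_granges(df),
                                           .as_granges(models$genes))
  qi <- S4Vectors::queryHits(body_hits)
  gi <- S4Vectors::subjectHits(body_hits)
  if (length(qi)) {
    by_q <- split(models$genes$gene_id[gi], qi)
    ids <- vapply(by_q, function(g) paste(sort(unique(g)), collapse = ","),
                  character(1))
    out$gene_ids[as.integer(names(by_q))] <- ids
  }

  # nearest gene for intergenic CNVRs
  inter <- which(out$category == "intergenic")
  if (length(inter) && nrow(models$genes) > 0L) {
    nearest <- GenomicRanges::distanceToNearest(
      .as_granges(df[inter, , drop = FALSE]), .as_granges(models$genes))
    qn <- S4Vectors::queryHits(nearest)
    out$nearest_gene[inter[qn]] <-
      models$genes$gene_id[S4Vectors::subjectHits(nearest)]
    out$distance_bp[inter[qn]] <- S4Vectors::mcols(nearest)$distance
  }
  out
}

#' Genes whose gene bodies overlap a CNVR
#'
#' A gene is CNVR-overlapping when its gene body intersects the region by
#' at least 1 bp.
#'
#' @param cnvrs a `cnvr_set` or CNVR data.frame.
#' @param models a `gene_models` object.
#' @return character vector of gene ids (sorted, unique) across all given
#'   CNVRs.
#' @export
overlapping_genes <- function(cnvrs, models) {
  df <- if (inherits(cnvrs, "cnvr_set")) cnvrs$cnvrs else cnvrs
  if (nrow(df) == 0L || nrow(models$genes) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(.as_granges(df),
                                      .as_granges(models$genes))
  sort(unique(models$genes$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Common and breed-specific CNVR-harboring gene sets
#'
#' @param breed_gene_sets named list (one per breed) of gene-id character
#'   vectors.
#' @return list with `common` (genes present in every breed) and
#'   `specific` (named list: genes found in exactly that one breed).
#'   Specific sets are pairwise disjoint and disjoint from the common set.
#' @export
gene_set_partition <- function(breed_gene_sets) {
  if (length(breed_gene_sets) < 2L)
    .stopf("gene_set_partition needs at least 2 breed gene sets")
  sets <- lapply(breed_gene_sets, unique)
  common <- sort(Reduce(intersect, sets))
  counts <- table(unlist(sets))
  singletons <- names(counts)[counts == 1L]
  specific <- lapply(sets, function(s) sort(intersect(s, singletons)))
  list(common = common, specific = specific)
}

#' Overlap report of CNVRs against labeled interval sets
#'
#' A CNVR hits a label (QTL trait or published study) when it intersects
#' any interval of that label by at least `min_overlap_bp` bases and at
#' least `min_overlap_frac` of the CNVR's own length.
#'
#' @param cnvrs a `cnvr_set` or CNVR data.frame.
#' @param intervals a labeled interval table from [read_interval_table()].
#' @param min_overlap_bp minimum intersection in bp (default 1).
#' @param min_overlap_frac minimum intersection as a fraction of CNVR
#'   length (default 0).
#' @return list with `per_label` (data.frame `label`, `n_cnvrs`: distinct
#'   CNVRs hitting the label) and `per_cnvr` (data.frame `cnvr_id`,
#'   `label`, one row per hit pair).
#' @export
interval_overlap_report <- function(cnvrs, intervals, min_overlap_bp = 1,
                                    min_overlap_frac = 0) {
  df <- if (inherits(cnvrs, "cnvr_set")) cnvrs$cnvrs else cnvrs
  empty <- list(
    per_label = data.frame(label = character(), n_cnvrs = integer(),
                           stringsAsFactors = FALSE),
    per_cnvr = data.frame(cnvr_id = character(), label = character(),
                          stringsAsFactors = FALSE)
  )
  if (nrow(df) == 0L || nrow(intervals) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(.as_granges(df),
                                      .as_granges(intervals))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(empty)
  ov <- .ov_len(df$start[qi], df$end[qi],
                intervals$start[si], intervals$end[si])
  ok <- ov >= min_overlap_bp &
        ov / (df$end[qi] - df$start[qi]) >= min_overlap_frac
  qi <- qi[ok]; si <- si[ok]
  if (length(qi) == 0L) return(empty)
  per_cnvr <- unique(data.frame(cnvr_id = df$cnvr_id[qi],
                                label = intervals$label[si],
                                stringsAsFactors = FALSE))
  per_cnvr <- per_cnvr[order(per_cnvr$cnvr_id, per_cnvr$label), ,
                       drop = FALSE]
  rownames(per_cnvr) <- NULL
  agg <- stats::aggregate(cnvr_id ~ label, per_cnvr,
                          function(x) length(unique(x)))
  per_label <- data.frame(label = agg$label, n_cnvrs = agg$cnvr_id,
                          stringsAsFactors = FALSE)
  per_label <- per_label[order(-per_label$n_cnvrs, per_label$label), ,
                         drop = FALSE]
  rownames(per_label) <- NULL
  list(per_label = per_label, per_cnvr = per_cnvr)
}
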