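models <- read_gene_models(write_gff3_fixture())

mk_cnvr <- function(chrom, start, end, id = sprintf("c%d", seq_along(start))) {
  data.frame(cnvr_id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("category assignment follows the fixed precedence", {
  # geneA (+): exons [1000,2001) & [4000,5001), CDS [1500,2001) & [4000,4501),
  # UTR5 [1000,1500), UTR3 [4501,5001), intron [2001,4000)
  cases <- list(
    list(mk_cnvr("chr1", 1600, 2500), "exonic"),    # spans CDS + intron
    list(mk_cnvr("chr1", 2001, 2003), "splicing"),  # first 2 bp of intron
    list(mk_cnvr("chr1", 3998, 4000), "splicing"),  # last 2 bp of intron
    list(mk_cnvr("chr1", 1100, 1400), "UTR5"),
    list(mk_cnvr("chr1", 4600, 4900), "UTR3"),
    list(mk_cnvr("chr1", 2500, 3500), "intronic"),  # deep intron
    list(mk_cnvr("chr1", 300, 600), "upstream"),    # within 1 kb before TSS
    list(mk_cnvr("chr1", 5200, 5600), "downstream"),
    list(mk_cnvr("chr1", 50000, 51000), "intergenic")
  )
  for (cs in cases) {
    expect_equal(annotate_context(cs[[1L]], models)$category, cs[[2L]],
                 info = cs[[2L]])
  }
  # non-coding geneB: exon overlap is exonic even without CDS
  expect_equal(annotate_context(mk_cnvr("chr1", 20100, 20200),
                                models)$category, "exonic")
})

test_that("flank windows are strand-aware", {
  # geneB is on the minus strand [20000, 21001): upstream lies to its right
  up <- annotate_context(mk_cnvr("chr1", 21200, 21500), models)
  expect_equal(up$category, "upstream")
  down <- annotate_context(mk_cnvr("chr1", 19500, 19800), models)
  expect_equal(down$category, "downstream")
})

test_that("intergenic CNVRs report the nearest gene and distance", {
  ann <- annotate_context(mk_cnvr("chr1", 10000, 11000), models)
  expect_equal(ann$category, "intergenic")
  expect_equal(ann$nearest_gene, "geneA")
  expect_true(is.finite(ann$distance_bp) && ann$distance_bp > 0)
  expect_equal(ann$gene_ids, "")
})

test_that("gene-body overlaps are reported independently of category", {
  # spans the tail of geneA and the head of geneB territory
  ann <- annotate_context(mk_cnvr("chr1", 4900, 20100), models)
  expect_equal(ann$gene_ids, "geneA,geneB")
  expect_equal(overlapping_genes(mk_cnvr("chr1", 4900, 20100), models),
               c("geneA", "geneB"))
  expect_equal(overlapping_genes(mk_cnvr("chr1", 2500, 2600), models),
               "geneA")  # intron still lies in the gene body
  expect_equal(overlapping_genes(mk_cnvr("chr1", 50000, 51000), models),
               character(0))
})

test_that("annotation is invariant to CNVR row order", {
  cnvrs <- mk_cnvr("chr1", c(1600, 2500, 50000), c(2500, 3500, 51000))
  a <- annotate_context(cnvrs, models)
  b <- annotate_context(cnvrs[3:1, ], models)
  expect_equal(a[order(a$cnvr_id), ]$category,
               b[order(b$cnvr_id), ]$category)
})

test_that("gene set partition separates common from breed-specific genes", {
  sets <- list(b1 = c("a", "b"), b2 = c("b", "c"))
  res <- gene_set_partition(sets)
  expect_equal(res$common, "b")
  expect_equal(res$specific$b1, "a")
  expect_equal(res$specific$b2, "c")
  same <- gene_set_partition(list(x = c("g1", "g2"), y = c("g1", "g2")))
  expect_equal(same$common, c("g1", "g2"))
  expect_equal(lengths(same$specific), c(x = 0L, y = 0L))
  # random sets: specifics pairwise disjoint, disjoint from common,
  # and |common| + sum |specific| <= |union|
  set.seed(3)
  many <- lapply(1:16, function(i)
    sample(sprintf("g%02d", 1:40), sample(5:20, 1)))
  names(many) <- sprintf("b%02d", 1:16)
  r <- gene_set_partition(many)
  all_spec <- unlist(r$specific)
  expect_equal(anyDuplicated(all_spec), 0L)
  expect_equal(intersect(all_spec, r$common), character(0))
  expect_lte(length(r$common) + length(all_spec),
             length(unique(unlist(many))))
  expect_error(gene_set_partition(list(only = "g")), "at least 2")
})

test_that("interval overlap report uses >= 1 bp half-open intersection", {
  g <- toy_genome()
  qtl <- data.frame(label = c("t1", "t1", "t2"), chrom = "chr1",
                    start = c(199, 300, 1000), end = c(300, 400, 2000),
                    stringsAsFactors = FALSE)
  cnvrs <- mk_cnvr("chr1", c(100, 100, 5000), c(200, 300, 6000))
  rep <- interval_overlap_report(cnvrs, qtl)
  # c1 [100,200) vs t1 [199,300): exactly 1 bp -> hit
  expect_true(any(rep$per_cnvr$cnvr_id == "c1" &
                  rep$per_cnvr$label == "t1"))
  # distinct CNVRs per label: c1 and c2 both hit t1
  expect_equal(rep$per_label$n_cnvrs[rep$per_label$label == "t1"], 2L)
  expect_false("t2" %in% rep$per_cnvr$label)
  # half-open abutment is no hit
  abut <- interval_overlap_report(
    mk_cnvr("chr1", 100, 200),
    data.frame(label = "t", chrom = "chr1", start = 200, end = 300))
  expect_equal(nrow(abut$per_cnvr), 0L)
  # empty inputs give empty reports
  expect_equal(nrow(interval_overlap_report(cnvrs, qtl[0L, ])$per_cnvr),
               0L)
})

test_that("overlap report equals a brute-force all-pairs oracle", {
  set.seed(21)
  for (rep_i in 1:10) {
    n <- sample(20:120, 1)
    cn <- random_intervals(n)
    cn$cnvr_id <- sprintf("c%03d", seq_len(n))
    iv <- random_intervals(sample(10:60, 1))
    iv$label <- sprintf("lab%d", sample.int(6, nrow(iv), replace = TRUE))
    got <- interval_overlap_report(cn, iv)$per_cnvr
    want <- brute_force_overlap_report(cn, iv)
    want <- want[order(want$cnvr_id, want$label), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("overlap criterion knobs tighten the report", {
  cnvrs <- mk_cnvr("chr1", 100, 1100)   # length 1000
  iv <- data.frame(label = "t", chrom = "chr1", start = 1050, end = 2000)
  expect_equal(nrow(interval_overlap_report(cnvrs, iv)$per_cnvr), 1L)
  expect_equal(nrow(interval_overlap_report(cnvrs, iv,
                                            min_overlap_bp = 100)$per_cnvr),
               0L)
  expect_equal(nrow(interval_overlap_report(cnvrs, iv,
                                            min_overlap_frac = 0.1)$per_cnvr),
               0L)
})
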