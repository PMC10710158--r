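test_that("Vst reproduces the analytic anchor cases", {
  expect_equal(vst(c(2, 2, 4), c(2, 2, 4))[["vst"]], 0)
  expect_equal(vst(c(0, 0, 0), c(2, 2, 2))[["vst"]], 1)
  r <- vst(c(2, 2, 4, 4), c(2, 2, 2, 2))
  expect_equal(r[["v_t"]], 0.75)
  expect_equal(r[["v_s"]], 0.5)
  expect_equal(r[["vst"]], 1 / 3)
  # all samples identical: zero total variance defines Vst = 0
  expect_equal(vst(c(2, 2), c(2, 2))[["vst"]], 0)
  expect_error(vst(2, c(2, 2)), "at least 2")
})

test_that("Vst matches a loop-based oracle and obeys its invariances", {
  set.seed(11)
  for (rep in 1:200) {
    a <- sample(0:6, sample(2:20, 1), replace = TRUE) +
      stats::rnorm(1, 0, 0.1)
    b <- sample(0:6, sample(2:20, 1), replace = TRUE)
    got <- vst(a, b)[["vst"]]
    expect_lt(abs(got - brute_force_vst(a, b)), 1e-12)
    # symmetry
    expect_lt(abs(got - vst(b, a)[["vst"]]), 1e-12)
    # shift and positive-scale invariance
    expect_lt(abs(got - vst(a + 3, b + 3)[["vst"]]), 1e-9)
    expect_lt(abs(got - vst(a * 2.5, b * 2.5)[["vst"]]), 1e-9)
  }
  # permutations of the same values give zero differentiation
  x <- c(0, 1, 2, 3, 4)
  expect_equal(vst(x, rev(x))[["vst"]], 0)
})

test_that("copy-number matrix cells are coverage-weighted means with diploid default", {
  g <- toy_genome()
  cohort <- list(
    cnvrs = data.frame(cnvr_id = "COHORT_chr1_1", chrom = "chr1",
                       start = 10001, end = 20001, level = "COHORT",
                       cnvr_type = "DEL", n_members = 1L, n_breeds = 1L,
                       breeds = "A", stringsAsFactors = FALSE),
    members = mk_calls("chr1", 10001, 20001, sample = "s1", pop = "A",
                       cn = 0)
  )
  class(cohort) <- "cnvr_set"
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        population_id = c("A", "A", "B"),
                        stringsAsFactors = FALSE)
  calls <- rbind(
    mk_calls("chr1", 10001, 15001, sample = "s1", pop = "A", cn = 0),
    mk_calls("chr1", 10001, 12001, sample = "s2", pop = "A", cn = 4),
    mk_calls("chr1", 12001, 20001, sample = "s2", pop = "A", cn = 3)
  )
  mat <- build_cn_matrix(cohort, calls, samples, g)
  # DEL CN0 over half the region: (0*5000 + 2*5000)/10000
  expect_equal(mat$cn["COHORT_chr1_1", "s1"], 1.0)
  # two calls covering 2 kb at CN4 and 8 kb at CN3
  expect_equal(mat$cn["COHORT_chr1_1", "s2"], 3.2)
  # no overlapping call: exactly diploid
  expect_equal(mat$cn["COHORT_chr1_1", "s3"], 2.0)
  expect_error(
    build_cn_matrix(cohort, mk_calls("chr1", 1, 1000, sample = "ghost"),
                    samples, g),
    "absent from the sample sheet")
})

test_that("the matrix is restricted to autosomal CNVRs", {
  g <- toy_genome()
  cnvrs <- data.frame(
    cnvr_id = c("COHORT_chr1_1", "COHORT_chrX_1"),
    chrom = c("chr1", "chrX"), start = 1, end = 10001, level = "COHORT",
    cnvr_type = "DEL", n_members = 1L, n_breeds = 1L, breeds = "A",
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(cnvrs = cnvrs, members = mk_calls("chr1", 1,
                                                             10001)),
                      class = "cnvr_set")
  samples <- data.frame(sample_id = c("s1", "s2"),
                        population_id = c("A", "B"))
  mat <- build_cn_matrix(cohort, mk_calls("chr1", 1, 10001)[0L, ],
                         samples, g)
  expect_equal(rownames(mat$cn), "COHORT_chr1_1")
})

test_that("pairwise Vst emits one record per CNVR in genome order", {
  g <- toy_genome()
  cnvrs <- data.frame(
    cnvr_id = sprintf("COHORT_chr1_%d", 1:3), chrom = "chr1",
    start = c(1, 20001, 40001), end = c(10001, 30001, 50001),
    level = "COHORT", cnvr_type = "DEL", n_members = 1L, n_breeds = 1L,
    breeds = "A", stringsAsFactors = FALSE
  )
  cohort <- structure(list(cnvrs = cnvrs,
                           members = mk_calls("chr1", 1, 10001)),
                      class = "cnvr_set")
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    population_id = rep(c("A", "B"), each = 3), stringsAsFactors = FALSE)
  # plant a fixed difference at the second CNVR only
  calls <- mk_calls("chr1", 20001, 30001,
                    sample = c("s1", "s2", "s3"), pop = "A", cn = 0)
  mat <- build_cn_matrix(cohort, calls, samples, g)
  rec <- pairwise_vst(mat, "A", "B")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$cnvr_id, cnvrs$cnvr_id)
  expect_equal(rec$vst, c(0, 1, 0))
  expect_true(all(rec$n_a == 3 & rec$n_b == 3))
  expect_error(pairwise_vst(mat, "A", "nope"), "not in matrix")
})

test_that("empirical threshold uses the nearest-rank top fraction with inclusive ties", {
  vals <- seq_len(200) / 200            # 200 distinct values
  thr <- empirical_threshold(vals, 0.01)
  expect_equal(thr$k, 2L)
  expect_equal(thr$threshold, 199 / 200)  # 2nd largest
  rec <- data.frame(cnvr_id = sprintf("c%d", 1:200), vst = vals,
                    selected = FALSE)
  sel <- select_differentiated(rec)
  expect_equal(sum(sel$selected), 2L)
  # n = 50, k = 1: the maximum
  thr50 <- empirical_threshold(seq_len(50), 0.01)
  expect_equal(thr50$k, 1L)
  expect_equal(thr50$threshold, 50)
  # all equal: everything ties at the threshold
  rec_eq <- data.frame(vst = rep(0.4, 10), selected = FALSE)
  expect_equal(sum(select_differentiated(rec_eq)$selected), 10L)
  expect_error(empirical_threshold(numeric(0)), "no finite")
})

test_that("selection respects explicit thresholds", {
  rec <- data.frame(vst = c(0, 0.2, 0.9), selected = FALSE)
  expect_equal(sum(select_differentiated(rec, threshold = 1.1)$selected),
               0L)
  expect_equal(sum(select_differentiated(rec, threshold = 0)$selected), 3L)
})

test_that("gene intersections across pairs report provenance", {
  sets <- list(p1 = c("g1", "g2"), p2 = c("g2", "g3"))
  res <- intersect_comparisons(sets)
  expect_equal(res$common, "g2")
  expect_equal(res$provenance$gene, c("g1", "g2", "g3"))
  expect_equal(res$provenance$p1, c(TRUE, TRUE, FALSE))
  expect_equal(intersect_comparisons(list(a = "x", b = "y"))$common,
               character(0))
  expect_equal(intersect_comparisons(list(a = c("x", "y"),
                                          b = c("x", "y")))$common,
               c("x", "y"))
})

test_that("empirical Vst converges to the analytic expectation with sample size", {
  # same locus distributions, growing cohorts; mean |error| must decrease
  p_a <- c(0.3, 0, 0.7)  # 30% homozygous deletion carriers
  p_b <- c(0, 0, 0.6, 0, 0.4)
  truth <- expected_vst(p_a, p_b)
  errs <- vapply(c(10, 50, 200), function(n) {
    set.seed(123)
    reps <- vapply(1:40, function(r) {
      a <- sample(0:2, n, TRUE, prob = p_a)
      b <- sample(0:4, n, TRUE, prob = p_b)
      vst(a, b)[["vst"]]
    }, numeric(1))
    mean(abs(reps - truth))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[[3L]], 0.05)
})
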