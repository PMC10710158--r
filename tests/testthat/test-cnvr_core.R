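test_that("length and placement filters use the documented boundaries", {
  g <- toy_genome()
  calls <- mk_calls("chr1", c(1000, 1000, 1000), c(1999, 2000, 2001))
  calls <- rbind(calls, mk_calls("chrUn_scaf1", 1000, 5000))
  res <- filter_calls(calls, g)
  # lengths 999 dropped, 1000 and 1001 kept; scaffold call dropped
  expect_equal(res$calls$end - res$calls$start, c(1000, 1001))
  expect_equal(res$drop_report$n_dropped,
               c(short = 1L, unplaced = 1L), ignore_attr = TRUE)
  empty <- filter_calls(calls[0L, ], g)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(sum(empty$drop_report$n_dropped), 0L)
})

test_that("reciprocal overlap fractions match hand arithmetic", {
  expect_equal(reciprocal_overlap(c(100, 200), c(150, 260)),
               c(frac_a = 0.5, frac_b = 50 / 110))
  expect_equal(reciprocal_overlap(c(100, 200), c(100, 200)),
               c(frac_a = 1, frac_b = 1))
  expect_equal(reciprocal_overlap(c(100, 200), c(120, 220)),
               c(frac_a = 0.8, frac_b = 0.8))
  expect_equal(reciprocal_overlap(c(100, 200), c(300, 400)),
               c(frac_a = 0, frac_b = 0))
  expect_error(
    reciprocal_overlap(mk_calls("chr1", 1, 10), mk_calls("chr2", 1, 10)),
    "different chromosomes")
})

test_that("recurrence filter keeps calls supported by >= 2 distinct samples", {
  calls <- rbind(
    mk_calls("chr1", 100, 200, sample = "s1"),
    mk_calls("chr1", 120, 220, sample = "s2"),   # reciprocal 0.8 with s1
    mk_calls("chr1", 500, 600, sample = "s3"),   # alone
    mk_calls("chr1", 100, 200, sample = "s1")    # same sample twice
  )
  kept <- recurrence_filter(calls)
  expect_setequal(unique(kept$sample_id), c("s1", "s2"))
  expect_equal(nrow(kept), 3L)  # the duplicate s1 call also matches s2
  # a call matched only within the same sample is not recurrent
  solo <- rbind(mk_calls("chr1", 100, 200, sample = "s1"),
                mk_calls("chr1", 100, 200, sample = "s1"),
                mk_calls("chr2", 100, 20000, sample = "s2"))
  expect_equal(nrow(recurrence_filter(solo)), 0L)
  # recurrence counts carriers of any CNV type
  mixed <- rbind(mk_calls("chr1", 100, 200, sample = "s1", cn = 1),
                 mk_calls("chr1", 100, 200, sample = "s2", cn = 3))
  expect_equal(nrow(recurrence_filter(mixed)), 2L)
})

test_that("a population with a single sample loses its calls with a warning", {
  calls <- rbind(mk_calls("chr1", 100, 200, sample = "s1", pop = "lonely"),
                 mk_calls("chr1", 100, 200, sample = "s2", pop = "ok"),
                 mk_calls("chr1", 110, 210, sample = "s3", pop = "ok"))
  expect_warning(kept <- recurrence_filter(calls), "lonely")
  expect_setequal(unique(kept$population_id), "ok")
})

test_that("reciprocal merging is single-linkage with union spans", {
  g <- toy_genome()
  # chain at exactly 0.5 reciprocal: one component spanning [0,200)
  # (half-open internal starts at 1, use 1-based equivalents)
  chain <- mk_calls("chr1", c(1, 51, 101), c(101, 151, 201),
                    sample = c("s1", "s2", "s3"))
  set1 <- merge_reciprocal(chain, g)
  expect_equal(nrow(set1$cnvrs), 1L)
  expect_equal(set1$cnvrs$start, 1)
  expect_equal(set1$cnvrs$end, 201)
  expect_equal(set1$cnvrs$n_members, 3L)
  # (0.5, 0.4545) fails the reciprocal criterion: two CNVRs, spans overlap
  pair <- mk_calls("chr1", c(100, 150), c(200, 260),
                   sample = c("s1", "s2"))
  set2 <- merge_reciprocal(pair, g)
  expect_equal(nrow(set2$cnvrs), 2L)
  # disjoint calls stay apart
  far <- mk_calls("chr1", c(100, 5000), c(1100, 6000),
                  sample = c("s1", "s2"))
  expect_equal(nrow(merge_reciprocal(far, g)$cnvrs), 2L)
  # empty input
  expect_equal(nrow(merge_reciprocal(chain[0L, ], g)$cnvrs), 0L)
})

test_that("merging partitions the calls and is permutation-invariant", {
  g <- toy_genome()
  set.seed(42)
  for (rep in 1:20) {
    calls <- random_intervals(60)
    a <- merge_reciprocal(calls, g)
    b <- merge_reciprocal(calls[sample.int(nrow(calls)), ], g)
    expect_equal(nrow(a$members), nrow(calls))           # partition
    expect_true(all(table(a$members$cnvr_id) >= 1))
    expect_equal(partition_signature(a), partition_signature(b))
    expect_identical(a$cnvrs, b$cnvrs)
    # spans cover every member
    m <- merge(a$members, a$cnvrs, by = "cnvr_id",
               suffixes = c("", ".r"))
    expect_true(all(m$start >= m$start.r & m$end <= m$end.r))
  }
})

test_that("merging agrees with a brute-force pairwise-edge oracle", {
  g <- toy_genome()
  set.seed(7)
  for (rep in 1:25) {
    calls <- random_intervals(sample(5:120, 1))
    got <- merge_reciprocal(calls, g)
    comp <- brute_force_components(calls)
    expect_equal(partition_signature(got),
                 signature_from_labels(calls, comp))
  }
})

test_that("CNVR classification follows member types and MIXED is absorbing", {
  expect_equal(classify_cnvr(c("DUP", "DUP")), "DUP")
  expect_equal(classify_cnvr("DEL"), "DEL")
  expect_equal(classify_cnvr(c("DUP", "DEL")), "MIXED")
  expect_equal(classify_cnvr(rev(c("DUP", "DEL", "DEL"))), "MIXED")
  expect_equal(classify_cnvr(c("MIXED-absorb" = "DUP", "DEL", "DUP")),
               "MIXED")
  expect_error(classify_cnvr(character(0)), "no members")
})

test_that("breed-to-cohort merge preserves provenance and recomputes class", {
  g <- toy_genome()
  a <- merge_reciprocal(mk_calls("chr1", c(100, 110), c(200, 210),
                                 sample = c("a1", "a2"), pop = "A",
                                 cn = 3.5), g)
  b <- merge_reciprocal(mk_calls("chr1", c(110, 120), c(210, 220),
                                 sample = c("b1", "b2"), pop = "B",
                                 cn = 0.5), g)
  cohort <- merge_breed_to_cohort(list(A = a, B = b), g)
  expect_equal(nrow(cohort$cnvrs), 1L)
  expect_equal(cohort$cnvrs$cnvr_type, "MIXED")
  expect_equal(cohort$cnvrs$n_breeds, 2L)
  expect_equal(cohort$cnvrs$breeds, "A,B")
  expect_equal(nrow(cohort$members), 4L)
  expect_equal(cohort$cnvrs$start, 100)
  expect_equal(cohort$cnvrs$end, 220)
  # single breed in: idempotent re-merge
  solo <- merge_breed_to_cohort(list(A = a), g)
  expect_equal(nrow(solo$cnvrs), nrow(a$cnvrs))
  expect_equal(solo$cnvrs$start, a$cnvrs$start)
  expect_equal(solo$cnvrs$end, a$cnvrs$end)
  # disjoint breed CNVRs concatenate
  c_set <- merge_reciprocal(mk_calls("chr2", c(5000, 5100), c(9000, 9100),
                                     sample = c("c1", "c2"), pop = "C"), g)
  both <- merge_breed_to_cohort(list(A = a, C = c_set), g)
  expect_equal(nrow(both$cnvrs), 2L)
})

test_that("summaries compute counts, lengths and genome coverage", {
  g <- genome_def("chr1", 1e6)
  cnvrs <- data.frame(
    cnvr_id = c("c1", "c2", "c3"), chrom = "chr1",
    start = c(1, 10001, 50001), end = c(1001, 13001, 55001),
    level = "COHORT", cnvr_type = c("DUP", "DEL", "MIXED"),
    n_members = 1L, n_breeds = 1L, breeds = "A",
    stringsAsFactors = FALSE
  )
  s <- summarize_cnvrs(cnvrs, g)
  expect_equal(s$n_cnvr, 3L)
  expect_equal(s$median_length, 3000)
  expect_equal(s$total_length, 9000)
  expect_equal(s$coverage_fraction, 0.009)
  # doubling the genome halves coverage with the CNVRs fixed
  g2 <- genome_def("chr1", 2e6)
  expect_equal(summarize_cnvrs(cnvrs, g2)$coverage_fraction,
               s$coverage_fraction / 2)
  zero <- summarize_cnvrs(cnvrs[0L, ], g)
  expect_equal(zero$n_cnvr, 0L)
  expect_equal(zero$coverage_fraction, 0)
})

test_that("length histogram bins by class and its fractions sum to one", {
  cnvrs <- data.frame(
    cnvr_id = sprintf("c%d", 1:3), chrom = "chr1",
    start = 0, end = c(1500, 2500, 12000),
    cnvr_type = c("DEL", "DUP", "MIXED"), stringsAsFactors = FALSE
  )
  h <- length_histogram(cnvrs)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$n_total[h$bin == "[1000,2000)"], 1L)
  expect_equal(h$n_total[h$bin == "[2000,4000)"], 1L)
  expect_equal(h$n_total[h$bin == "[10000,20000)"], 1L)
  expect_equal(h$n_dup[h$bin == "[2000,4000)"], 1L)
  # per-class stacks sum to the bin totals
  expect_equal(h$n_total, h$n_dup + h$n_del + h$n_mixed)
  # a CNVR below the first edge lands in the flagged underflow bin
  tiny <- cnvrs; tiny$end <- 500
  expect_warning(h2 <- length_histogram(tiny), "underflow")
  expect_equal(h2$n_total[h2$underflow], 3L)
  # empty set, and degenerate single-bin occupancy
  h3 <- length_histogram(cnvrs[0L, ])
  expect_equal(sum(h3$n_total), 0L)
  one_bin <- cnvrs; one_bin$end <- c(1100, 1200, 1300)
  h4 <- length_histogram(one_bin)
  expect_equal(h4$fraction[h4$bin == "[1000,2000)"], 1)
  expect_error(length_histogram(cnvrs, bin_edges = c(5, 2)),
               "increasing")
})
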