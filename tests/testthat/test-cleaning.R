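# Sample QC exclusion, gap merging, length cap and the cohort summary.

test_that("sample QC excludes on strict thresholds with named reasons", {
  qc <- sample_qc(
    sprintf("S%d", 1:5),
    lrr_sd = c(0.29, 0.31, 0.30, 0.10, 0.10),
    baf_drift = c(0.004, 0.001, 0.005, 0.006, 0.002),
    wave_factor = c(0.05, 0.0, 0.1, 0.0, -0.2)
  )
  res <- filter_samples_by_qc(qc, clean_config())
  # boundary values (0.30, 0.005, 0.1) are kept: "larger than" is strict
  expect_setequal(res$kept, c("S1", "S3"))
  expect_equal(res$excluded$reasons[res$excluded$sample_id == "S2"], "LRR_SD")
  expect_equal(res$excluded$reasons[res$excluded$sample_id == "S4"], "BAF_DRIFT")
  expect_equal(res$excluded$reasons[res$excluded$sample_id == "S5"], "WAVE_FACTOR")
  expect_error(filter_samples_by_qc(sample_qc(c("S1", "S1"), 0.1, 0.001, 0)),
               "duplicate")
})

test_that("gap merging follows the 20%-of-span rule", {
  # gap 100 over span 2000: ratio 0.05 < 0.2, merged
  a <- cnv_calls("S1", "1", c(1L, 1101L), c(1000L, 2000L), 1L, n_snp = c(5L, 7L))
  m <- merge_adjacent_calls(a, 0.2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 2000L))
  expect_equal(m$n_snp, 12L)
  # gap 1000 over span 3000: ratio 0.333, unmerged
  b <- cnv_calls("S1", "1", c(1L, 2001L), c(1000L, 3000L), 1L)
  expect_equal(nrow(merge_adjacent_calls(b, 0.2)), 2L)
  # different copy number never merges
  d <- cnv_calls("S1", "1", c(1L, 1101L), c(1000L, 2000L), c(1L, 3L))
  expect_equal(nrow(merge_adjacent_calls(d, 0.2)), 2L)
  # overlapping same-state calls merge unconditionally, with a warning
  e <- cnv_calls("S1", "1", c(1L, 500L), c(1000L, 1500L), 1L)
  expect_warning(me <- merge_adjacent_calls(e, 0.2), "unconditionally")
  expect_equal(nrow(me), 1L)
})

test_that("gap merging is idempotent and matches the pairwise oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    start <- sort(sample.int(5000, n))
    len <- sample.int(800, n)
    g <- cnv_calls("S1", "1", start, start + len, 1L, n_snp = 1L)
    g <- suppressWarnings(merge_adjacent_calls(g, 1e-9))  # de-overlap first
    m1 <- merge_adjacent_calls(g, 0.2)
    expect_identical(as.data.frame(merge_adjacent_calls(m1, 0.2)),
                     as.data.frame(m1))
    oracle <- oracle_merge_group(as.data.frame(g), 0.2)
    expect_equal(m1$start, oracle$start)
    expect_equal(m1$end, oracle$end)
    expect_equal(m1$n_snp, oracle$n_snp)
  }
})

test_that("merging only adds gap bases to the covered span", {
  set.seed(77)
  calls <- random_calls(50)
  calls <- suppressWarnings(merge_adjacent_calls(calls, 1e-9))
  merged <- merge_adjacent_calls(calls, 0.2)
  # per (sample, chrom, cn) group the merged span contains every original call
  expect_true(sum(cnv_length(merged)) >= sum(cnv_length(calls)))
  expect_true(nrow(merged) <= nrow(calls))
})

test_that("length cap drops strictly-longer-than-5Mb calls and partitions", {
  calls <- cnv_calls("S1", "1", c(1L, 1L, 1L), c(5000000L, 5000001L, 100L), 1L)
  res <- drop_long_cnvs(calls, 5)
  expect_equal(nrow(res$kept), 2L)   # exactly 5 Mb is kept
  expect_equal(res$dropped$end, 5000001L)
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(calls))
})

test_that("planted 6-Mb artifacts are exactly what the length cap removes", {
  set.seed(5)
  sim <- simulate_cohort(test_sim_config(seed = 9))
  cl <- cnv_clean(sim$calls$penncnv, sim$qc)
  truth_art <- sim$truth$long_artifacts$penncnv
  qc_fail <- sim$truth$qc_fail_samples
  expected <- truth_art[!(truth_art$sample_id %in% qc_fail), ]
  expect_equal(nrow(cl$dropped_long), nrow(expected))
  expect_setequal(cl$dropped_long$sample_id, expected$sample_id)
  expect_true(all(cnv_length(cl$calls) <= 5e6))
})

test_that("cohort summary gets counts, means and length stats right", {
  # single call: mean = 1/n, min = max = mean length
  one <- cnv_calls("S1", "1", 1L, 100L, 3L)
  s <- summarize_cnvs(one, 10)
  expect_equal(s$cnvs_per_individual, 0.1)
  expect_equal(s$per_state$mean_length, 100)
  expect_equal(s$per_state$min_length, s$per_state$max_length)

  set.seed(21)
  calls <- random_calls(200, n_samples = 20)
  s2 <- summarize_cnvs(calls, 20)
  expect_equal(sum(s2$per_state$n), nrow(calls))
  expect_equal(s2$cnvs_per_individual * 20, nrow(calls))
  expect_equal(sum(s2$length_bins$n), nrow(calls))
  expect_error(summarize_cnvs(calls, 0), "positive")
})
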