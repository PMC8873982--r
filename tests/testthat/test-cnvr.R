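# CNVR calling: connected-component semantics, classification, frequency
# counting and summaries.

test_that("singletons, 1-bp touches and gaps behave per the overlap rule", {
  one <- cnv_calls("S1", "1", 100L, 200L, 1L)
  r1 <- call_cnvr(one)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end, r1$n_samples), c(100L, 200L, 1L))

  # 200-300 shares bp 200 with 100-200 -> merged; 400-500 is separate
  calls <- cnv_calls(c("S1", "S2", "S3"), "1",
                     c(100L, 200L, 400L), c(200L, 300L, 500L), 1L)
  r <- call_cnvr(calls)
  expect_equal(nrow(r), 2L)
  expect_equal(r$n_samples, c(2L, 1L))
  expect_equal(c(r$start[1], r$end[1]), c(100L, 300L))

  # adjacency without a shared bp (end 200, start 201) does NOT merge
  adj <- cnv_calls(c("S1", "S2"), "1", c(100L, 201L), c(200L, 300L), 1L)
  expect_equal(nrow(call_cnvr(adj)), 2L)
})

test_that("region type is gain/loss/mixed by member copy numbers", {
  expect_equal(classify_cnv_type(c(3L, 4L)), "gain")
  expect_equal(classify_cnv_type(c(0L, 1L)), "loss")
  expect_equal(classify_cnv_type(c(1L, 3L)), "mixed")
  expect_error(classify_cnv_type(integer()), "empty")
  expect_error(classify_cnv_type(c(1L, 2L)), "impossible")
})

test_that("call_cnvr matches the union-find oracle on random inputs", {
  set.seed(202)
  for (rep in 1:60) {
    calls <- random_calls(sample(1:40, 1))
    got <- call_cnvr(calls)
    exp <- oracle_cnvr(calls)
    expect_equal(got$chrom, exp$chrom)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$type, exp$type)
    expect_equal(got$n_calls, exp$n_calls)
    expect_equal(got$n_samples, exp$n_samples)
  }
})

test_that("call_cnvr is idempotent and order-invariant", {
  set.seed(303)
  calls <- random_calls(80)
  r1 <- call_cnvr(calls)
  # permuted input gives the identical region set
  perm <- calls[sample(nrow(calls)), ]
  r2 <- call_cnvr(perm)
  expect_equal(as.data.frame(r1), as.data.frame(r2), ignore_attr = TRUE)
  # re-merging the regions themselves (as pseudo-calls) changes nothing
  pseudo <- cnv_calls(r1$region_id, r1$chrom, r1$start, r1$end,
                      ifelse(r1$type == "loss", 1L, 3L))
  r3 <- call_cnvr(pseudo)
  expect_equal(r3$start, r1$start)
  expect_equal(r3$end, r1$end)
})

test_that("every call lands in exactly one region", {
  set.seed(404)
  calls <- random_calls(60)
  regions <- call_cnvr(calls)
  assignment <- attr(regions, "assignment")
  expect_equal(length(assignment), nrow(calls))
  expect_true(all(assignment >= 1L & assignment <= nrow(regions)))
  # each call is inside its region's span
  expect_true(all(calls$start >= regions$start[assignment] &
                    calls$end <= regions$end[assignment]))
  expect_equal(sum(regions$n_calls), nrow(calls))
  expect_true(all(regions$n_samples <= regions$n_calls))
})

test_that("mixed-assembly and unknown-chromosome inputs error", {
  calls <- cnv_calls(c("S1", "S2"), "1", c(1L, 50L), c(10L, 60L), 1L,
                     build = c("ARS", "UMD"))
  expect_error(call_cnvr(calls), "assemblies")
  g <- genome_build("test", c(`1` = 1000))
  r <- call_cnvr(cnv_calls("S1", "2", 1L, 10L, 1L))
  expect_error(cnvr_summary(r, g), "absent")
})

test_that("summary totals, per-type partition and coverage are consistent", {
  set.seed(505)
  g <- genome_build("test", stats::setNames(rep(1e4, 3), 1:3))
  calls <- random_calls(50)
  regions <- call_cnvr(calls)
  s <- cnvr_summary(regions, g)
  expect_equal(sum(s$per_type$n), s$total_count)
  expect_equal(sum(s$per_type$total_length), s$total_length_bp)
  expect_equal(s$genome_coverage_pct,
               100 * s$total_length_bp / genome_length(g))
  # one region of length L on a genome of length 100L -> 1% coverage
  g2 <- genome_build("toy", c(`1` = 1e5))
  r2 <- call_cnvr(cnv_calls("S1", "1", 1L, 1000L, 1L))
  expect_equal(cnvr_summary(r2, g2)$genome_coverage_pct, 1.0)
})

test_that("planted regions are recovered with high overlap under mild jitter", {
  sim <- simulate_cohort(test_sim_config(seed = 31,
                                         breakpoint_jitter_frac = 0.03,
                                         fp_call_rate = 0,
                                         long_artifact_rate = 0,
                                         qc_fail_frac = 0,
                                         caller_detection_prob = c(penncnv = 1,
                                                                   cnvpartition = 1)))
  cl <- cnv_clean(sim$calls$penncnv, sim$qc)
  regions <- call_cnvr(cl$calls)
  arch <- sim$truth$archetypes
  for (i in seq_len(nrow(arch))) {
    if (arch$n_carriers[i] == 0) next
    hit <- regions[regions$chrom == arch$chrom[i] &
                     regions$start <= arch$end[i] & regions$end >= arch$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_gte(jaccard(hit$start, hit$end, arch$start[i], arch$end[i]), 0.9)
  }
})
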