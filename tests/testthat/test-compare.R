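# Call-level and region-level comparison, consensus calling, database
# cross-validation and artifact flagging.

test_that("individual-level overlap requires the same sample", {
  a <- cnv_calls("S1", "1", 100L, 200L, 1L)
  b_same <- cnv_calls("S1", "1", 150L, 250L, 1L)
  b_other <- cnv_calls("S2", "1", 100L, 200L, 1L)
  r1 <- compare_cnv(a, b_same, "individual")
  expect_equal(r1$pct_overlapped, c(100, 100))
  expect_equal(r1$n_same_state, c(1L, 1L))
  r2 <- compare_cnv(a, b_other, "individual")
  expect_equal(r2$pct_overlapped, c(0, 0))
  r3 <- compare_cnv(a, b_other, "population")
  expect_equal(r3$pct_overlapped, c(100, 100))
})

test_that("swapping arguments swaps the per-direction numbers exactly", {
  set.seed(606)
  a <- random_calls(30); b <- random_calls(25)
  ab <- compare_cnv(a, b, "individual")
  ba <- compare_cnv(b, a, "individual")
  expect_equal(ab$n_overlapped, rev(ba$n_overlapped))
  expect_equal(ab$n_total, rev(ba$n_total))
})

test_that("overlap counts equal the all-pairs oracle at both levels", {
  set.seed(707)
  for (rep in 1:20) {
    a <- random_calls(sample(5:30, 1))
    b <- random_calls(sample(5:30, 1))
    for (level in c("individual", "population")) {
      got <- compare_cnv(a, b, level)
      exp <- oracle_compare_cnv(a, b, level)
      expect_equal(got$n_overlapped, unname(exp))
    }
    # population-level percentage always >= individual-level
    pop <- compare_cnv(a, b, "population")
    ind <- compare_cnv(a, b, "individual")
    expect_true(all(pop$pct_overlapped >= ind$pct_overlapped))
  }
})

test_that("CNVR comparison uses union accounting for overlapped length", {
  a <- tibble::tibble(region_id = "A1", chrom = "1", start = 100L, end = 300L,
                      type = "loss", n_samples = 5L)
  b <- tibble::tibble(region_id = c("B1", "B2"), chrom = "1",
                      start = c(200L, 250L), end = c(400L, 350L),
                      type = "loss", n_samples = c(3L, 2L))
  res <- compare_cnvr(a, b)
  expect_equal(res$report$n_a_hit, 1L)
  expect_equal(res$report$n_b_hit, 2L)
  # union of 200-300 and 250-300 is 101 bp, not 152
  expect_equal(res$report$overlap_length_bp, 101)
  expect_equal(nrow(res$pairs), 2L)
  expect_true(all(res$pairs$frac_a > 0 & res$pairs$frac_a <= 1))

  ident <- compare_cnvr(a, a)
  expect_equal(ident$report$pct_length_a, 100)
  expect_equal(ident$report$pct_b_hit, 100)
})

test_that("overlapped length matches the per-basepair oracle and its bounds", {
  set.seed(808)
  for (rep in 1:15) {
    a <- random_regions(sample(3:15, 1), prefix = "A")
    b <- random_regions(sample(3:15, 1), prefix = "B")
    res <- compare_cnvr(a, b)
    expect_equal(res$report$overlap_length_bp, oracle_overlap_length(a, b, 2e4))
    expect_lte(res$report$overlap_length_bp,
               min(sum(a$end - a$start + 1), sum(b$end - b$start + 1)))
  }
})

test_that("consensus threshold is the ceiling of min cohort times proportion", {
  expect_equal(consensus_threshold(393, 0.05), 20L)  # 19.65 rounds up
  expect_equal(consensus_threshold(400, 0.05), 20L)
  expect_equal(consensus_threshold(100, 0.05), 5L)
  expect_equal(consensus_threshold(c(403, 393, 397), 0.05), 20L)
  expect_error(consensus_threshold(integer()), "non-empty")
})

test_that("consensus counts each sample once across callers", {
  samples <- sprintf("S%d", 1:10)
  penn <- cnv_calls(samples, "1", 1000L, 2000L, 1L, caller = "penncnv")
  part <- cnv_calls(samples, "1", 1100L, 2100L, 1L, caller = "cnvpartition")
  cs <- consensus_cnvrs(list(penn, part), 10L)
  expect_equal(nrow(cs$regions), 1L)
  expect_equal(cs$regions$n_samples, 10L)  # 20 calls, 10 distinct samples
  expect_equal(cs$regions$n_calls, 20L)
  # 19 carriers at threshold 20 are excluded
  cs2 <- consensus_cnvrs(list(penn[1:9, ], part), 20L)
  expect_equal(nrow(cs2$regions), 0L)
  # assembly mismatch errors
  bad <- cnv_calls("S1", "1", 1L, 10L, 1L, build = "other")
  expect_error(consensus_cnvrs(list(penn, bad), 1L), "assemblies")
})

test_that("consensus of a single list at threshold 1 reproduces call_cnvr", {
  set.seed(909)
  calls <- random_calls(40)
  cs <- consensus_cnvrs(list(calls), 1L)
  direct <- call_cnvr(calls, source = "union")
  expect_equal(as.data.frame(cs$regions), as.data.frame(direct), ignore_attr = TRUE)
})

test_that("database cross-validation counts hits, specifics and length", {
  study <- tibble::tibble(region_id = c("R1", "R2"), chrom = "1",
                          start = c(100L, 1000L), end = c(200L, 1100L),
                          type = "loss", n_samples = 2L)
  external <- tibble::tibble(region_id = "E1", chrom = "1",
                             start = 50L, end = 250L, type = "loss",
                             n_samples = 1L)
  rep1 <- compare_to_database(study, external)
  expect_equal(rep1$n_study_hit, 1L)
  expect_equal(rep1$n_study_specific, 1L)
  expect_equal(rep1$overlap_length_bp, 101)  # study R1 fully inside E1
  # disjoint -> all study regions population-specific
  far <- tibble::tibble(region_id = "E2", chrom = "2", start = 1L, end = 10L,
                        type = "gain", n_samples = 1L)
  rep2 <- compare_to_database(study, far)
  expect_equal(rep2$n_study_hit, 0L)
  expect_equal(rep2$n_study_specific, 2L)
  # random sets agree with the per-bp oracle
  set.seed(111)
  a <- random_regions(10, prefix = "S"); b <- random_regions(12, prefix = "D")
  expect_equal(compare_to_database(a, b)$overlap_length_bp,
               oracle_overlap_length(a, b, 2e4))
})

test_that("artifact flagging hits inside intervals, not 1 bp past them", {
  study <- tibble::tibble(region_id = c("R1", "R2", "R3"), chrom = "1",
                          start = c(100L, 501L, 300L), end = c(200L, 600L, 450L),
                          type = "loss", n_samples = 1L)
  blacklist <- tibble::tibble(id = "BL1", chrom = "1", start = 50L, end = 500L)
  flagged <- flag_known_artifacts(study, blacklist)
  expect_setequal(flagged$region_id, c("R1", "R3"))  # R2 starts 1 bp past
  expect_equal(unique(flagged$blacklist_id), "BL1")
})
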