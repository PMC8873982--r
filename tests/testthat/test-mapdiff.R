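# Manifest comparison: category partition, density, order concordance.

test_that("marker pairs fall in exactly one of the seven categories", {
  a <- snp_map(c("m1", "m2", "m3", "m4", "m6"),
               c("5", NA, "1", NA, "2"),
               c(100L, NA, 50L, NA, 10L))
  b <- snp_map(c("m1", "m2", "m3", "m4", "m5"),
               c("5", "3", "2", NA, "1"),
               c(120L, 30L, 60L, NA, 99L))
  res <- classify_marker_pairs(a, b)
  per <- stats::setNames(res$per_marker$category, res$per_marker$name)
  expect_equal(unname(per[c("m1", "m2", "m3", "m4", "m5", "m6")]),
               c("same_chromosome", "unknown_in_A", "different_chromosomes",
                 "both_unknown", "missing_from_A", "missing_from_B"))
  # the categories partition the union of marker names
  expect_equal(sum(res$counts$n), length(union(a$name, b$name)))
})

test_that("self-comparison yields only same-chromosome and both-unknown", {
  set.seed(12)
  mp <- simulate_map_pair(test_sim_config(seed = 12))
  res <- classify_marker_pairs(mp$map_a, mp$map_a)
  nonzero <- res$counts$category[res$counts$n > 0]
  expect_true(all(nonzero %in% c("same_chromosome", "both_unknown")))
})

test_that("swapping maps swaps the asymmetric categories", {
  mp <- simulate_map_pair(test_sim_config(seed = 13))
  ab <- classify_marker_pairs(mp$map_a, mp$map_b)$counts
  ba <- classify_marker_pairs(mp$map_b, mp$map_a)$counts
  g <- function(x, k) x$n[x$category == k]
  expect_equal(g(ab, "unknown_in_A"), g(ba, "unknown_in_B"))
  expect_equal(g(ab, "missing_from_A"), g(ba, "missing_from_B"))
  expect_equal(g(ab, "same_chromosome"), g(ba, "same_chromosome"))
  expect_equal(g(ab, "different_chromosomes"), g(ba, "different_chromosomes"))
})

test_that("planted category counts are recovered exactly", {
  mp <- simulate_map_pair(test_sim_config(seed = 14))
  got <- classify_marker_pairs(mp$map_a, mp$map_b)$counts
  truth <- table(mp$truth$category)
  for (k in got$category) {
    expect_equal(got$n[got$category == k],
                 if (k %in% names(truth)) as.integer(truth[[k]]) else 0L,
                 info = k)
  }
})

test_that("SNP density is markers per Mb with explicit length source", {
  g <- genome_build("t", c(`1` = 1e7, `2` = 1e7))
  map <- snp_map(sprintf("m%d", 1:500), "1",
                 as.integer(seq(2e4, 1e7, length.out = 500)))
  expect_warning(d <- snp_density(map, g), "no mapped markers")
  expect_equal(d$snps_per_mb[d$chrom == "1"], 50)
  expect_equal(d$snps_per_mb[d$chrom == "2"], 0)
  # max-position proxy when no genome given
  d2 <- snp_density(map)
  expect_equal(d2$length_source, "max_position")
  expect_equal(d2$length_bp, 1e7)
})

test_that("order discordance counts flipped pairs, zero for identical maps", {
  pos <- as.integer(c(10, 20, 30, 40, 50))
  a <- snp_map(sprintf("m%d", 1:5), "1", pos)
  same <- position_concordance(a, a)
  expect_equal(same$discordance$n_discordant_pairs, 0)
  # one swapped neighbour pair -> exactly 1 discordant pair
  b <- snp_map(sprintf("m%d", 1:5), "1", as.integer(c(10, 30, 20, 40, 50)))
  one <- position_concordance(a, b)
  expect_equal(one$discordance$n_discordant_pairs, 1)
})

test_that("discordant-pair counts match the exhaustive oracle", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    pos_a <- sort(sample.int(1e6, n))
    pos_b <- sample(pos_a)
    a <- snp_map(sprintf("m%d", 1:n), "7", pos_a)
    b <- snp_map(sprintf("m%d", 1:n), "7", pos_b)
    got <- position_concordance(a, b)$discordance$n_discordant_pairs
    expect_equal(got, oracle_discordant_pairs(pos_a, pos_b))
  }
})

test_that("cross-chromosome markers are reported separately for plotting", {
  a <- snp_map(c("m1", "m2"), c("1", "1"), c(10L, 20L))
  b <- snp_map(c("m1", "m2"), c("1", "2"), c(12L, 99L))
  res <- position_concordance(a, b)
  expect_equal(res$cross_chromosome$name, "m2")
  expect_equal(res$pairs$name, "m1")
})
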