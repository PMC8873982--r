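# Gene annotation, carrier frequencies, consensus genes and name-based
# cross-assembly comparison.

test_that("gene hits use inclusive 1-bp overlap arithmetic", {
  genes <- gene_table(c("G1", "G2"), "1", c(100L, 100L), c(200L, 200L))
  calls <- cnv_calls(c("S1", "S2"), "1", c(150L, 201L), c(300L, 300L), 1L)
  res <- annotate_genes(calls, genes[1, ], cohort_size = 10)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$overlap_bp, 51L)   # 150..200 inclusive
  expect_equal(res$per_gene$n_samples, 1L)
  expect_equal(res$per_gene$frequency_pct, 10)
  # the call starting at 201 misses a gene ending at 200
  res2 <- annotate_genes(calls[2, ], genes, cohort_size = 10)
  expect_equal(nrow(res2$hits), 0L)
})

test_that("hit sets equal the exhaustive all-pairs scan and ignore order", {
  set.seed(23)
  for (rep in 1:10) {
    calls <- random_calls(sample(5:25, 1))
    ng <- sample(3:10, 1)
    gs <- sample.int(9000, ng)
    genes <- gene_table(sprintf("G%d", seq_len(ng)),
                        sample(as.character(1:3), ng, replace = TRUE),
                        gs, gs + sample.int(1500, ng))
    res <- annotate_genes(calls, genes, cohort_size = 5)
    brute <- 0L
    for (i in seq_len(ng)) for (j in seq_len(nrow(calls))) {
      if (genes$chrom[i] == calls$chrom[j] &&
          genes$tx_start[i] <= calls$end[j] && calls$start[j] <= genes$tx_end[i])
        brute <- brute + 1L
    }
    expect_equal(nrow(res$hits), brute)
    shuffled <- annotate_genes(calls[sample(nrow(calls)), ], genes, cohort_size = 5)
    expect_equal(res$per_gene, shuffled$per_gene)
  }
})

test_that("consensus genes threshold on distinct carriers, inclusive", {
  per_gene <- tibble::tibble(gene_name = c("A", "B", "C"), chrom = "1",
                             n_cnvs = c(30L, 25L, 40L),
                             n_samples = c(20L, 19L, 21L),
                             frequency_pct = c(5.0, 4.8, 5.3))
  kept <- consensus_genes(per_gene, 20L)
  expect_setequal(kept$gene_name, c("A", "C"))  # 20 kept at threshold 20
})

test_that("genes planted inside frequent regions pass, background genes fail", {
  sim <- simulate_cohort(ideal_sim_config(seed = 51, jitter = 0.02))
  cl_p <- cnv_clean(sim$calls$penncnv, sim$qc)
  cl_c <- cnv_clean(sim$calls$cnvpartition, sim$qc)
  pooled <- dplyr::bind_rows(cl_p$calls, cl_c$calls)
  th <- consensus_threshold(sim$config$n_samples, 0.05)
  ann <- annotate_genes(pooled, sim$genes, sim$config$n_samples)
  kept <- consensus_genes(ann$per_gene, th)
  placement <- sim$truth$gene_placement
  arch <- sim$truth$archetypes
  frequent <- arch$region_id[arch$n_carriers >= th]
  expected <- placement$gene_name[placement$region_id %in% frequent]
  expect_setequal(kept$gene_name, expected)
  expect_false(any(grepl("^BG_GENE", kept$gene_name)))
  # every consensus gene sits inside a consensus-strength region here
  regions <- call_cnvr(pooled)
  checked <- check_genes_in_consensus_regions(kept, sim$genes, regions, th)
  expect_true(all(checked$in_consensus_region))
})

test_that("cross-build gene comparison partitions the union", {
  res <- compare_genes_across_builds(c("GBP4", "CERS6", "STK39"),
                                     c("gbp4", "NOSTRIN"))
  expect_setequal(toupper(res$shared), "GBP4")
  expect_setequal(res$a_only, c("CERS6", "STK39"))
  expect_setequal(res$b_only, "NOSTRIN")
  expect_equal(res$union_size, 4L)
  expect_equal(length(res$shared) + length(res$a_only) + length(res$b_only),
               res$union_size)
  # identical sets leave nothing unique
  same <- compare_genes_across_builds(c("A", "B"), c("B", "A"))
  expect_equal(length(same$a_only), 0L)
  expect_equal(length(same$b_only), 0L)
  # synonym map harmonizes aliases before comparing
  syn <- compare_genes_across_builds("LOC100848815", "BOLA-DQA1",
                                     synonyms = c(LOC100848815 = "BOLA-DQA1"))
  expect_equal(length(syn$shared), 1L)
  expect_equal(syn$union_size, 1L)
})

test_that("random name sets agree with direct set algebra", {
  set.seed(29)
  for (rep in 1:10) {
    a <- sample(sprintf("G%02d", 1:30), sample(5:20, 1))
    b <- sample(sprintf("G%02d", 1:30), sample(5:20, 1))
    res <- compare_genes_across_builds(a, b)
    expect_setequal(res$shared, intersect(a, b))
    expect_setequal(res$a_only, setdiff(a, b))
    expect_setequal(res$b_only, setdiff(b, a))
    expect_equal(res$union_size, length(union(a, b)))
  }
})
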