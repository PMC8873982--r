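#!/usr/bin/env Rscript
# Stage 5: gene annotation and consensus genes.
#
# Annotates the pooled (union-set) calls against the refGene-style table,
# computes per-gene carrier frequencies, keeps the genes reaching the same
# >= 5%-of-cohort bar used for consensus CNVRs, and cross-checks that each
# consensus gene sits inside a consensus-strength region.

suppressMessages({library(cnvrkit); library(dplyr)})

read_calls <- function(k)
  validate_cnv_calls(utils::read.delim(
    sprintf("results/clean/calls_%s.tsv", k),
    colClasses = list(chrom = "character", sample_id = "character")))
pooled <- bind_rows(read_calls("penncnv"), read_calls("cnvpartition"))
genes <- read_refgene("results/sim_input/refgene.txt")
n_samples <- nrow(read_sample_qc("results/sim_input/sample_qc.tsv"))
th <- consensus_threshold(n_samples, 0.05)

ann <- annotate_genes(pooled, genes, cohort_size = n_samples)
kept <- consensus_genes(ann$per_gene, th)
regions <- call_cnvr(pooled, "union")
checked <- check_genes_in_consensus_regions(kept, genes, regions, th)

message(sprintf("%d of %d annotated genes pass the >= %d-carrier bar (%.1f%%)",
                nrow(kept), nrow(ann$per_gene), th,
                proportion_pct(nrow(kept), max(nrow(ann$per_gene), 1))))
print(as.data.frame(checked))

dir.create("results/genes", showWarnings = FALSE, recursive = TRUE)
utils::write.table(ann$per_gene, "results/genes/gene_frequency.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(checked, "results/genes/consensus_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
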