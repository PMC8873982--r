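#!/usr/bin/env Rscript
# Stage 3: merge cleaned calls into population CNVRs per caller.
#
# Regions are connected components of the >=1-bp overlap graph; each is
# typed gain/loss/mixed and carries its distinct-sample frequency. Writes
# BED + TSV per caller and the per-type / genome-coverage summaries.

suppressMessages(library(cnvrkit))

cfg <- sim_config(seed = 20260926L %% .Machine$integer.max)
genome <- sim_genome(cfg)

dir.create("results/cnvr", showWarnings = FALSE, recursive = TRUE)
for (k in c("penncnv", "cnvpartition")) {
  calls <- validate_cnv_calls(
    utils::read.delim(sprintf("results/clean/calls_%s.tsv", k),
                      colClasses = list(chrom = "character", sample_id = "character")))
  regions <- call_cnvr(calls, source = k)
  s <- cnvr_summary(regions, genome)
  message(sprintf("%s: %d CNVRs, total %.2f Mb (%.2f%% genome coverage)",
                  k, s$total_count, s$total_length_bp / 1e6, s$genome_coverage_pct))
  print(s$per_type)
  write_cnvr_bed(regions, sprintf("results/cnvr/cnvr_%s.bed", k))
  utils::write.table(s$per_type, sprintf("results/cnvr/cnvr_summary_%s.tsv", k),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$per_chrom, sprintf("results/cnvr/cnvr_coverage_%s.tsv", k),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
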