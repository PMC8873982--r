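#!/usr/bin/env Rscript
# Stage 2: post-calling QC and cohort summaries.
#
# Reads both callers' raw lists, removes QC-failing samples (LRR SD > 0.30,
# BAF drift > 0.005, |wave factor| > 0.1), gap-merges fragmented PennCNV
# calls (gap < 20% of the merged span), drops calls > 5 Mb, and writes the
# per-state cohort summary tables.

suppressMessages(library(cnvrkit))

qc <- read_sample_qc("results/sim_input/sample_qc.tsv")
raw <- list(
  penncnv = read_penncnv_calls("results/sim_input/penncnv.rawcnv", "sim"),
  cnvpartition = read_cnvpartition_calls("results/sim_input/cnvpartition.txt", "sim")
)
n_samples <- nrow(qc)

dir.create("results/clean", showWarnings = FALSE, recursive = TRUE)
for (k in names(raw)) {
  cl <- cnv_clean(raw[[k]], qc)
  n_eff <- n_samples - nrow(cl$excluded_samples)
  s <- summarize_cnvs(cl$calls, n_eff)
  message(sprintf("%s: %d raw -> %d cleaned calls (%d long calls dropped); %.2f CNVs/individual over %d individuals",
                  k, nrow(raw[[k]]), nrow(cl$calls), nrow(cl$dropped_long),
                  round_half_up(s$cnvs_per_individual, 2), n_eff))
  print(s$per_state)
  utils::write.table(cl$calls, sprintf("results/clean/calls_%s.tsv", k),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$per_state, sprintf("results/clean/cnv_summary_%s.tsv", k),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cl$excluded_samples, "results/clean/excluded_samples.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
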