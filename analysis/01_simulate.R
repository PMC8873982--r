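#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates a 400-animal SNP-array cohort over 29 autosomes with eight
# planted CNV loci (gain / loss / mixed, population frequencies 0.01-0.30),
# two callers with different sensitivities, paired SNP manifests with
# planted cross-assembly discrepancies, a refGene-style gene set and
# per-sample QC records. All downstream stages read the files written here.

suppressMessages(library(cnvrkit))

seed <- 20260926L %% .Machine$integer.max
cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)

dir.create("results/sim_input", showWarnings = FALSE, recursive = TRUE)
files <- write_cohort(sim, "results/sim_input")

arch <- sim$truth$archetypes
message(sprintf("cohort: %d samples, %d autosomes x %.0f Mb",
                cfg$n_samples, cfg$n_autosomes, cfg$chrom_length_bp / 1e6))
message(sprintf("planted %d CNV loci; carrier counts: %s",
                nrow(arch), paste(arch$n_carriers, collapse = ", ")))
message(sprintf("caller call counts: penncnv=%d cnvpartition=%d",
                nrow(sim$calls$penncnv), nrow(sim$calls$cnvpartition)))
message("wrote: ", paste(basename(files), collapse = ", "))
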