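#!/usr/bin/env Rscript
# Stage 7: publication-style figures.
#
# The CNVR distribution map (region glyphs by type, consensus regions
# underlined, per-chromosome coverage in the axis labels) and a manifest
# dot plot for the chromosome with the most order discordance.

suppressMessages(library(cnvrkit))

cfg <- sim_config(seed = 20260926L %% .Machine$integer.max)
genome <- sim_genome(cfg)

union_regions <- read_cnvr_bed("results/compare/union_cnvr.bed")
consensus <- read_cnvr_bed("results/compare/consensus_cnvr.bed")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
render_cnvr_map(union_regions, consensus, genome,
                "results/figures/cnvr_map.png")
message(sprintf("CNVR map: %d regions, %d consensus marks -> results/figures/cnvr_map.png",
                nrow(union_regions), nrow(consensus)))

map_a <- read_snp_map("results/sim_input/map_a.tsv")
map_b <- read_snp_map("results/sim_input/map_b.tsv")
conc <- position_concordance(map_a, map_b)
worst <- conc$discordance$chrom[which.max(conc$discordance$n_discordant_pairs)]
render_map_dotplot(conc, worst,
                   sprintf("results/figures/map_dotplot_chr%s.png", worst))
message(sprintf("manifest dot plot for chr%s -> results/figures/", worst))
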