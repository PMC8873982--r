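#!/usr/bin/env Rscript
# Stage 4: cross-caller comparison and consensus CNVR calling.
#
# Compares the two callers' calls at the individual and population level
# (population overlap is always at least individual overlap), compares
# their CNVR lists with union-length accounting, then pools both call sets
# and keeps union-set CNVRs carried by >= 5% of the cohort.

suppressMessages(library(cnvrkit))

read_calls <- function(k)
  validate_cnv_calls(utils::read.delim(
    sprintf("results/clean/calls_%s.tsv", k),
    colClasses = list(chrom = "character", sample_id = "character")))
penn <- read_calls("penncnv")
part <- read_calls("cnvpartition")
n_samples <- nrow(read_sample_qc("results/sim_input/sample_qc.tsv"))

dir.create("results/compare", showWarnings = FALSE, recursive = TRUE)

cnv_cmp <- rbind(compare_cnv(penn, part, "individual"),
                 compare_cnv(penn, part, "population"))
message("call-level overlap (penncnv vs cnvpartition):")
print(cnv_cmp)
utils::write.table(cnv_cmp, "results/compare/compare_cnv.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

regions <- list(penncnv = call_cnvr(penn, "penncnv"),
                cnvpartition = call_cnvr(part, "cnvpartition"))
cnvr_cmp <- compare_cnvr(regions$penncnv, regions$cnvpartition)
message(sprintf("CNVR overlap: %d/%d penncnv vs %d/%d cnvpartition regions hit; %.2f Mb overlapped (%.1f%% / %.1f%% of each side)",
                cnvr_cmp$report$n_a_hit, cnvr_cmp$report$n_a,
                cnvr_cmp$report$n_b_hit, cnvr_cmp$report$n_b,
                cnvr_cmp$report$overlap_length_bp / 1e6,
                cnvr_cmp$report$pct_length_a, cnvr_cmp$report$pct_length_b))
utils::write.table(cnvr_cmp$report, "results/compare/compare_cnvr.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cnvr_cmp$pairs, "results/compare/compare_cnvr_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

th <- consensus_threshold(n_samples, 0.05)
cs <- consensus_cnvrs(list(penn, part), th)
message(sprintf("consensus: %d of %d union CNVRs reach >= %d carriers",
                nrow(cs$regions), nrow(cs$union_regions), th))
print(cs$regions[, c("region_id", "chrom", "start", "end", "type", "n_samples")])
write_cnvr_bed(cs$union_regions, "results/compare/union_cnvr.bed")
write_cnvr_bed(cs$regions, "results/compare/consensus_cnvr.bed")
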