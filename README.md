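# cnvrkit

Post-calling copy number variant (CNV) analysis for SNP-array cohorts.

Array-based CNV studies in livestock (and elsewhere) end up with raw call
lists from one or more callers — typically PennCNV and
CNVPartition/GenomeStudio — possibly against more than one genome assembly.
Everything scientifically interesting happens *after* calling: quality
filtering, merging per-sample calls into population CNV regions (CNVRs),
deciding which regions are reproducible across callers, annotating genes,
and reconciling results across assembly versions whose SNP manifests
disagree. cnvrkit implements that downstream half as a tested R package
plus a numbered analysis workflow, with a synthetic-cohort generator so the
whole pipeline is verifiable without any external data.

## What it computes

* **Cleaning** — per-sample signal QC (exclude when LRR SD > 0.30, BAF
  drift > 0.005, or |wave factor| > 0.1; strict inequalities), gap-merging
  of fragmented same-state calls (merge when gap < 20% of the merged
  span), and a 5 Mb length cap.
* **CNVRs** — regions are the connected components of the ≥1-bp
  interval-overlap graph per chromosome. A region is *gain* if every
  member call has copy number > 2, *loss* if every member has < 2, and
  *mixed* otherwise; its frequency is the count of distinct carrier
  samples.
* **Consensus CNVRs** — pool both callers' calls, re-merge, and keep
  regions with at least `ceiling(min cohort size × 0.05)` carriers
  (20 of ~400).
* **Comparison** — directional call overlap at individual level (same
  sample required) and population level (sample ignored; always ≥ the
  individual rate); region overlap with union-length accounting (shared
  bases never double-counted); database-style cross-validation and
  artifact-blacklist flagging.
* **Genes** — refGene-based annotation, per-gene distinct-carrier
  frequency, consensus genes at the same 5% bar, and name-based gene-set
  comparison across assemblies.
* **Manifest comparison** — partition of the marker union into seven
  concordance categories, per-chromosome SNP density, and per-chromosome
  order-discordance counts.
* **Simulator** — planted CNVR archetypes with per-sample penetrance,
  breakpoint jitter, per-caller detection, false positives, QC failures,
  and paired manifests with planted discrepancies, all recorded in a truth
  manifest.

## Worked example

```r
library(cnvrkit)

cfg <- sim_config(seed = 7, n_samples = 100)  # 29 x 10 Mb autosomes
sim <- simulate_cohort(cfg)

cl_penn <- cnv_clean(sim$calls$penncnv,      sim$qc)
cl_part <- cnv_clean(sim$calls$cnvpartition, sim$qc)

th <- consensus_threshold(100, 0.05)   # ceiling(100 * 0.05) = 5 carriers
cs <- consensus_cnvrs(list(cl_penn$calls, cl_part$calls), th)
cs
#> Consensus set: 5 of 15 union CNVRs with >= 5 carriers (callers: penncnv, cnvpartition)
cs$regions[, c("chrom", "start", "end", "type", "n_samples")]
#>   chrom   start     end  type n_samples
#> 1     1 1994724 2305585  loss        39
#> 2     2 4992172 5407125 mixed        18
#> 3     3  997377 1152977  gain        16
#> 4     5 6996034 7203799  loss        10
#> 5     8 2954327 3254431 mixed         7
```

The five consensus regions are exactly the planted loci whose realized
carrier counts reached the 5-carrier bar (the cohort's truth manifest,
`sim$truth$archetypes`, lists carrier counts 40, 20, 18, 11, 6, 2, 3, 1
for the eight planted loci), each recovered with its planted type and
distinct-carrier count, with boundaries spanning the union of the jittered
member calls.

The same stages run file-based as a workflow:

```sh
Rscript analysis/01_simulate.R          # write caller files + truth
Rscript analysis/02_clean_summarize.R   # QC, merge, cap; per-state tables
Rscript analysis/03_cnvr.R              # CNVRs per caller + coverage
Rscript analysis/04_compare_consensus.R # cross-caller overlap, consensus
Rscript analysis/05_genes.R             # gene frequencies, consensus genes
Rscript analysis/06_mapdiff.R           # manifest categories, density, order
Rscript analysis/07_figures.R           # CNVR map, manifest dot plot
```

Each script prints what it found and writes its tables under `results/`.

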