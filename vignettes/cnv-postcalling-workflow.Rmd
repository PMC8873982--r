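---
title: "Post-calling CNV analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-calling CNV analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cnvrkit implements the downstream half of a SNP-array CNV study: it starts
where the callers (PennCNV, CNVPartition) stop, and ends with
population-level consensus regions and genes that can be compared across
callers and across genome assemblies. This vignette explains the procedures,
the parameters that matter, and the choices made where the conventions of
the field leave room.

## The data model

A **CNV call** is one event in one sample: a 1-based closed interval on a
chromosome, an integer copy number in {0, 1, 3, 4} (a diploid state is not a
variant and is rejected at parse time), a supporting probe count, an
optional caller confidence, and caller/assembly labels. The closed-interval
convention matches the caller outputs being parsed; the BED exporter
converts to 0-based half-open coordinates, so BED width always equals
internal length.

A **CNVR** (CNV region) is a population-level object: the connected
component of the per-chromosome interval-overlap graph over calls, where two
calls are linked when they share at least one base pair. Two calls that
merely touch end-to-start share no base and are *not* linked — this is the
one place where the closed-interval arithmetic genuinely matters, and both
the implementation and its test oracle (a union-find over an all-pairs
overlap scan) enforce it. A region is typed **gain** when every member call
is a duplication (cn > 2), **loss** when every member is a deletion
(cn < 2), and **mixed** otherwise. A region's *frequency* is its number of
distinct carrier samples, not its raw call count: one animal reported by two
callers, or twice by one caller, counts once. Both counts are reported.

## Cleaning

Three filters run before any population-level step, in this order:

1. **Sample QC.** A sample is excluded when its Log R Ratio standard
   deviation exceeds 0.30, its B-allele-frequency drift exceeds 0.005, or
   its absolute genomic wave factor exceeds 0.1. All comparisons are
   strict, following the "larger than" phrasing these thresholds are
   conventionally stated with: a sample sitting exactly on a threshold is
   kept. These statistics are inputs (the callers compute them); cnvrkit
   does not recompute them from signal.
2. **Gap merging** (PennCNV lists only). The HMM caller fragments long
   events; two neighbouring same-state calls are rejoined when the gap
   between them is less than 20% of the total length of the merged result.
   The reference phrase "total length of the CNVs" is ambiguous about the
   denominator; we take the full span from the first call's start to the
   second call's end (both calls plus the gap), with the
   summed-lengths-only alternative selectable via
   `clean_config(merge_denominator = "lengths")`. The sweep runs
   left-to-right and iterates to a fixed point, which makes the result
   deterministic and insensitive to input order; idempotence is tested.
   CNVPartition output is not merged by default — its segmentation does not
   produce the fragmented runs the merge is meant to heal, and the
   reference workflow applies the merge only to the HMM caller's output.
3. **Length cap.** Calls strictly longer than 5 Mb are discarded. On array
   data these are nearly always chromosome-scale artifacts; the simulator
   plants exactly this class of artifact so the test suite can verify that
   the cap removes precisely the planted calls and nothing else.

Report rounding is half-away-from-zero (2 dp for means, 1 dp for
percentages), matching how such tables are conventionally printed; R's
default banker's rounding would disagree on exact halves.

## Consensus calling

The union set pools the cleaned calls of both callers and re-merges them
into CNVRs, which directly yields the complementary region list. The
consensus set keeps the union regions whose distinct-carrier count reaches
`ceiling(min(cohort sizes) × 0.05)` — with ~400 animals, 20 carriers. The
threshold is inclusive (`>= 20`): where the two conventional phrasings
("at least" vs "more than") conflict, we follow the rule as defined with
the explicit ceiling calculation, and the proportion is a parameter, so
either convention is reachable. Thresholding by distinct samples rather
than calls is deliberate: the rule is phrased as a sample count, and call
counts double-count animals seen by both callers.

## Comparison operations

Call-level comparison is directional and runs at two scopes: at the
**individual** level a call is overlapped only by a same-sample call
sharing at least 1 bp (this measures method agreement); at the
**population** level sample identity is ignored (this measures locus
repeatability). Population overlap is provably at least individual overlap,
and the property suite asserts it on random cohorts. A call overlapping
several partners counts once.

Region-level comparison reports all intersecting pairs plus a length
report. The overlapped length is the length of the intersection of the two
coverage unions — equivalently the union of all pairwise intersections —
so shared bases are never double-counted and the overlapped length can
never exceed either side's total. The accounting convention for the
published overlapped-length figures is unstated; union accounting is the
only choice with these invariants, and it is verified against a
per-basepair mask oracle.

Gene annotation intersects calls (or regions) with transcript-union gene
intervals; per-gene frequency counts distinct carrier samples among
intersecting *calls*. Because breakpoints vary between carriers, a gene
inside a frequent region can itself be hit in fewer samples — which is why
consensus genes are a subset of the genes in consensus regions, and why
the package reports, per consensus gene, whether it is backed by a
consensus-strength region. With per-sample calls and equal thresholds this
check passes on coherent data; it can fail in principle when the calls
hitting a gene split across several weak regions, so it is a reported
flag, not an assertion.

Cross-assembly gene comparison is by name (case-insensitive, optional
synonym map) because region coordinates cannot be compared across builds
without a liftover step, which is out of scope; gene symbols are assumed
stable across annotation snapshots.

## Manifest comparison

Two manifests of one array under different assemblies are compared by
partitioning the union of marker names into seven categories (same
chromosome, both unplaced, different chromosomes, unplaced in exactly one,
absent from exactly one). "Same chromosome" deliberately ignores position:
order disagreement is summarized separately as a Kendall-style
discordant-pair count per chromosome (computed by mergesort inversion
counting, checked against an O(n²) scan). The numeric discordance summary
is this package's addition — the underlying comparison is conventionally
only visualized — and is labelled as such. Unplaced-marker sentinels
(chromosome "0", "", "NA", "Un*", position <= 0) are configurable because
manifest exports differ. SNP density uses assembly chromosome lengths when
a genome file is supplied and falls back to the last mapped position,
flagged in the output, since the correct denominator choice depends on
information a manifest alone does not carry.

## The simulator

`simulate_cohort()` generates the whole input bundle — caller-format call
lists, paired manifests, refGene-style genes, QC records — plus a truth
manifest. Its defaults are the study conditions the test suite runs under:

* 400 samples, 29 autosomes of 10 Mb, 2 kb marker spacing. Desk scale: the
  genome is ~3.4% of a real bovine genome, chosen so the full pipeline and
  suite run in seconds while keeping a realistic per-chromosome marker
  count and multi-chromosome structure.
* Eight planted CNVR archetypes (gain/loss/mixed) with frequencies 0.30
  down to 0.01, bracketing the 5% consensus threshold on both sides, so
  threshold behaviour is exercised in both directions.
* Copy-number draws follow the qualitative array pattern — states 1 and 3
  common, 0 and 4 rare — as a convention, not as published rates.
* Breakpoint jitter: each carrier call's ends move uniformly by up to 2%
  (default) of region length; recovery properties are tested up to the 5%
  envelope, where the worst-case truth-vs-recovered Jaccard is still
  ≥ 0.90.
* Caller detection probabilities default to 0.9 (penncnv) and 0.6
  (cnvpartition), reflecting that HMM callers report several-fold more
  calls than segmentation callers on the same data; false-positive
  singletons arrive at 0.05 per sample per caller; 2% of samples receive
  failing QC statistics; 2% receive a 6-Mb artifact call.
* Manifest discrepancy rates default to the characteristic pattern of an
  old-vs-new assembly pair: ~89% same-chromosome, ~10% unplaced in the
  older map, with rare cross-chromosome moves, drops and local reorderings.

What the simulator does *not* emulate: linkage disequilibrium, relatedness,
genotype-intensity signal (LRR/BAF values sufficient to run the callers
themselves), and chromosome-length heterogeneity. Passing tests therefore
demonstrate the correctness of the post-calling arithmetic and the
recovery behaviour of the pipeline under controlled noise — not the
sensitivity of the upstream callers on real intensity data.

## Numerical and degenerate-input choices

* Merging overlapping same-state calls within one sample (which a caller
  should not emit) merges them unconditionally with a warning rather than
  failing.
* An empty call file parses to an empty table with a warning; malformed
  lines and missing columns are hard errors naming the offender.
* Region ids are assigned in (chromosome, start) order after numeric-aware
  chromosome sorting, so ids are stable across runs.
* `conf` of a merged call is the minimum of its members (the conservative
  choice); `NA` confidences propagate as `NA` rather than poisoning the
  minimum.
* Percent denominators are guarded: empty comparisons report `NA`
  percentages with a warning rather than dividing by zero.

## Problem sizes

The test suite and the acceptance script run the interval oracles on
1,000 random instances of ≤ 25 calls on small (5 kb–20 kb) genomes, the
pipeline properties on the 400-sample desk-scale cohort, and the
manifest comparison on the full ~145,000-marker grid — sizes chosen as the
smallest at which every code path (multi-chromosome, multi-caller,
threshold boundary) is exercised. Everything scales through `sim_config()`.

## Known limitations

* No liftover: cross-assembly region comparison is only via shared gene
  names or a marker-anchored mapping the user supplies; coordinate
  conversion failures are therefore out of scope by design.
* CNVR boundaries are the union of member calls; no breakpoint
  re-estimation from signal.
* The per-gene frequency uses calls, so genes longer than the typical call
  can accumulate carriers from non-overlapping calls; the consensus-region
  cross-check reports this situation rather than resolving it.
* Statistical enrichment of overlaps (permutation testing) is deliberately
  not provided; the comparison reports are descriptive.
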