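# Synthetic-cohort generator. Emits everything the pipeline consumes —
# caller-format CNV lists, paired SNP manifests with planted discrepancies,
# a refGene-style table, per-sample QC records — together with a ground
# truth manifest, so every stage can be tested against known answers.

#' Default planted CNVR archetypes
#'
#' A spread of gain-only, loss-only and mixed loci across chromosomes with
#' population frequencies from common (0.30) down to rare (0.01),
#' bracketing the usual 5% consensus threshold on both sides.
#'
#' @return A tibble: `region_id`, `chrom`, `start`, `end`, `type`,
#'   `target_frequency`.
#' @export
default_archetypes <- function() {
  tibble::tibble(
    region_id = sprintf("TRUE_%d", 1:8),
    chrom = as.character(c(1, 2, 3, 5, 8, 12, 15, 20)),
    start = as.integer(c(2e6, 5e6, 1e6, 7e6, 3e6, 4e6, 6e6, 2.5e6) + 1L),
    end = as.integer(c(2.3e6, 5.4e6, 1.15e6, 7.2e6, 3.25e6, 4.12e6, 6.2e6, 2.6e6)),
    type = c("loss", "mixed", "gain", "loss", "mixed", "gain", "loss", "gain"),
    target_frequency = c(0.30, 0.25, 0.15, 0.08, 0.06, 0.05, 0.02, 0.01)
  )
}

#' Simulation configuration
#'
#' Desk-scale defaults: 29 autosomes of 10 Mb each, 400 samples, ~2 kb
#' marker spacing — small enough that the full pipeline runs in seconds but
#' structured like a real array cohort. Copy-number states follow the usual
#' array pattern: single-copy losses and three-copy gains dominate, nullizygous
#' and four-copy calls are rare.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces outputs exactly.
#' @param n_autosomes,chrom_length_bp Genome shape.
#' @param n_samples Cohort size.
#' @param snp_spacing_bp Marker grid spacing.
#' @param cnvr_archetypes Planted regions, see [default_archetypes()].
#' @param breakpoint_jitter_frac Per-carrier breakpoint jitter as a fraction
#'   of region length (uniform, each end independently).
#' @param fp_call_rate Mean number of false-positive singleton calls per
#'   sample per caller (Poisson).
#' @param caller_detection_prob Named per-caller detection probability for a
#'   true carrier call.
#' @param long_artifact_rate Per-sample probability of one 6-Mb artifact
#'   call (the class the length cap exists to remove).
#' @param qc_fail_frac Fraction of samples given failing signal-quality
#'   statistics.
#' @param map_discrepancy_rates Named per-marker category probabilities for
#'   the manifest pair (`different_chromosomes`, `unknown_in_A`,
#'   `unknown_in_B`, `both_unknown`, `missing_from_A`, `missing_from_B`,
#'   `shuffled`); the remainder is concordant.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 29L,
                       chrom_length_bp = 1e7,
                       n_samples = 400L,
                       snp_spacing_bp = 2000L,
                       cnvr_archetypes = default_archetypes(),
                       breakpoint_jitter_frac = 0.02,
                       fp_call_rate = 0.05,
                       caller_detection_prob = c(penncnv = 0.9, cnvpartition = 0.6),
                       long_artifact_rate = 0.02,
                       qc_fail_frac = 0.02,
                       map_discrepancy_rates = c(different_chromosomes = 0.002,
                                                 unknown_in_A = 0.10,
                                                 unknown_in_B = 0.004,
                                                 both_unknown = 0.002,
                                                 missing_from_A = 0.004,
                                                 missing_from_B = 0.001,
                                                 shuffled = 0.01)) {
  stopifnot(n_autosomes >= 1, chrom_length_bp > 0, n_samples >= 1,
            snp_spacing_bp >= 1,
            breakpoint_jitter_frac >= 0, breakpoint_jitter_frac < 0.5,
            fp_call_rate >= 0, long_artifact_rate >= 0,
            qc_fail_frac >= 0, qc_fail_frac < 1,
            all(caller_detection_prob >= 0), all(caller_detection_prob <= 1),
            all(map_discrepancy_rates >= 0))
  if (sum(map_discrepancy_rates) > 1)
    stop("map discrepancy rates sum to more than 1")
  if (any(cnvr_archetypes$target_frequency <= 0) ||
      any(cnvr_archetypes$target_frequency > 1))
    stop("archetype frequencies must be in (0, 1]")
  if (any(cnvr_archetypes$end > chrom_length_bp) ||
      any(cnvr_archetypes$start < 1))
    stop("archetype span exceeds chromosome bounds")
  if (!all(cnvr_archetypes$chrom %in% as.character(seq_len(n_autosomes))))
    stop("archetype chromosome outside 1..n_autosomes")
  structure(list(seed = as.integer(seed), n_autosomes = as.integer(n_autosomes),
                 chrom_length_bp = chrom_length_bp,
                 n_samples = as.integer(n_samples),
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 cnvr_archetypes = cnvr_archetypes,
                 breakpoint_jitter_frac = breakpoint_jitter_frac,
                 fp_call_rate = fp_call_rate,
                 caller_detection_prob = caller_detection_prob,
                 long_artifact_rate = long_artifact_rate,
                 qc_fail_frac = qc_fail_frac,
                 map_discrepancy_rates = map_discrepancy_rates),
            class = "sim_config")
}

#' Genome build implied by a simulation config
#'
#' @param cfg A [sim_config()].
#' @param name Build label.
#' @return A [genome_build()].
#' @export
sim_genome <- function(cfg, name = "sim") {
  genome_build(name, stats::setNames(rep(cfg$chrom_length_bp, cfg$n_autosomes),
                                     as.character(seq_len(cfg$n_autosomes))))
}

# one cn draw per carrier: common states dominate
draw_cn <- function(type, n) {
  draw_loss <- function(k) ifelse(stats::runif(k) < 0.9, 1L, 0L)
  draw_gain <- function(k) ifelse(stats::runif(k) < 0.95, 3L, 4L)
  switch(type,
         loss = draw_loss(n),
         gain = draw_gain(n),
         mixed = {
           is_loss <- stats::runif(n) < 0.5
           # a mixed region must actually contain both classes when it can
           if (n >= 2L && length(unique(is_loss)) == 1L) is_loss[1] <- !is_loss[1]
           out <- integer(n)
           out[is_loss] <- draw_loss(sum(is_loss))
           out[!is_loss] <- draw_gain(sum(!is_loss))
           out
         })
}

jitter_breaks <- function(start, end, frac, chrom_len) {
  len <- end - start + 1L
  j <- function() as.integer(round(stats::runif(length(start), -frac * len, frac * len)))
  s <- pmax(1L, start + j())
  e <- pmin(as.integer(chrom_len), end + j())
  swap <- s > e
  if (any(swap)) { tmp <- s[swap]; s[swap] <- e[swap]; e[swap] <- tmp }
  list(start = s, end = e)
}

#' Simulate a CNV cohort with ground truth
#'
#' For each planted archetype, carriers are drawn i.i.d. at the target
#' frequency; each carrier produces a call with jittered breakpoints and a
#' copy number consistent with the archetype type. Each caller observes
#' each true call with its detection probability (breakpoint jitter is
#' drawn per caller). False-positive singleton calls and occasional 6-Mb
#' artifact calls are added, and a fraction of samples receive failing
#' signal-quality statistics. The truth manifest records every planted
#' fact.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort`: `calls` (named list of `cnv_calls`
#'   per caller), `qc`, `genes`, `map_a`, `map_b`, `genome`, and `truth`
#'   (list: `archetypes` with carrier lists, `fp_calls`, `long_artifacts`,
#'   `qc_fail_samples`, `map_categories`, `gene_placement`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  arch <- cfg$cnvr_archetypes

  # per-sample QC records; failing samples get out-of-range statistics
  n_fail <- round(cfg$qc_fail_frac * cfg$n_samples)
  fail_idx <- if (n_fail > 0) sample(cfg$n_samples, n_fail) else integer()
  qc <- sample_qc(
    samples,
    lrr_sd = ifelse(seq_len(cfg$n_samples) %in% fail_idx,
                    stats::runif(cfg$n_samples, 0.35, 0.6),
                    stats::runif(cfg$n_samples, 0.05, 0.25)),
    baf_drift = stats::runif(cfg$n_samples, 0, 0.004),
    wave_factor = stats::runif(cfg$n_samples, -0.08, 0.08)
  )

  carriers <- lapply(seq_len(nrow(arch)), function(i)
    samples[stats::runif(cfg$n_samples) < arch$target_frequency[i]])
  true_calls <- dplyr::bind_rows(lapply(seq_len(nrow(arch)), function(i) {
    ids <- carriers[[i]]
    if (!length(ids)) return(NULL)
    tibble::tibble(region_id = arch$region_id[i], sample_id = ids,
                   chrom = arch$chrom[i], start = arch$start[i],
                   end = arch$end[i],
                   cn = draw_cn(arch$type[i], length(ids)))
  }))

  observe <- function(caller) {
    det <- cfg$caller_detection_prob[[caller]]
    seen <- true_calls[stats::runif(nrow(true_calls)) < det, ]
    jb <- jitter_breaks(seen$start, seen$end, cfg$breakpoint_jitter_frac,
                        cfg$chrom_length_bp)
    planted <- cnv_calls(
      seen$sample_id, seen$chrom, jb$start, jb$end, seen$cn,
      n_snp = pmax(3L, as.integer(round((jb$end - jb$start + 1L) / cfg$snp_spacing_bp))),
      conf = round(stats::runif(nrow(seen), 40, 100), 1),
      caller = caller, build = "sim"
    )
    # false-positive singletons: short calls scattered uniformly
    n_fp <- stats::rpois(1L, cfg$fp_call_rate * cfg$n_samples)
    fp <- if (n_fp > 0) {
      len <- as.integer(round(stats::runif(n_fp, 1e4, 1e5)))
      st <- as.integer(floor(stats::runif(n_fp, 1, cfg$chrom_length_bp - len)))
      cnv_calls(sample(samples, n_fp, replace = TRUE),
                as.character(sample(cfg$n_autosomes, n_fp, replace = TRUE)),
                st, st + len - 1L,
                sample(c(0L, 1L, 3L, 4L), n_fp, replace = TRUE,
                       prob = c(0.05, 0.45, 0.45, 0.05)),
                n_snp = pmax(3L, as.integer(round(len / cfg$snp_spacing_bp))),
                conf = round(stats::runif(n_fp, 40, 100), 1),
                caller = caller, build = "sim")
    } else planted[0, ]
    # chromosome-scale artifacts the length cap is there to remove
    art_idx <- which(stats::runif(cfg$n_samples) < cfg$long_artifact_rate)
    art <- if (length(art_idx)) {
      cnv_calls(samples[art_idx],
                as.character(sample(cfg$n_autosomes, length(art_idx), replace = TRUE)),
                1L, 6000000L, 1L,
                n_snp = as.integer(6e6 / cfg$snp_spacing_bp),
                conf = 99, caller = caller, build = "sim")
    } else planted[0, ]
    list(calls = dplyr::bind_rows(planted, fp, art), fp = fp, artifacts = art)
  }
  obs <- lapply(stats::setNames(nm = names(cfg$caller_detection_prob)), observe)

  maps <- simulate_map_pair(cfg)
  genes <- simulate_genes(cfg)

  structure(list(
    calls = lapply(obs, `[[`, "calls"),
    qc = qc,
    genes = genes$genes,
    map_a = maps$map_a, map_b = maps$map_b,
    genome = sim_genome(cfg),
    truth = list(
      archetypes = dplyr::mutate(arch, carriers = carriers,
                                 n_carriers = lengths(carriers)),
      fp_calls = lapply(obs, `[[`, "fp"),
      long_artifacts = lapply(obs, `[[`, "artifacts"),
      qc_fail_samples = samples[fail_idx],
      map_categories = maps$truth,
      shuffled_markers = maps$shuffled_markers,
      gene_placement = genes$placement
    ),
    config = cfg
  ), class = "sim_cohort")
}

#' Simulate a pair of SNP manifests with planted discrepancies
#'
#' Markers sit on a regular grid in map A; each marker independently draws
#' a discrepancy category for map B at the configured rates: moved to a
#' different chromosome, position unknown in one or both maps, absent from
#' one map, or locally reordered (swapped with its grid neighbour in B).
#' The returned truth labels use the same seven categories that
#' [classify_marker_pairs()] reports (a locally reordered marker is still
#' `same_chromosome`).
#'
#' @param cfg A [sim_config()].
#' @return A list with `map_a`, `map_b`, `truth` (tibble: name, category)
#'   and `shuffled_markers`.
#' @export
simulate_map_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  grid <- expand.grid(
    chrom = as.character(seq_len(cfg$n_autosomes)),
    pos = seq(cfg$snp_spacing_bp, cfg$chrom_length_bp, by = cfg$snp_spacing_bp),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(as.integer(grid$chrom), grid$pos), ]
  n <- nrow(grid)
  name <- sprintf("SNP%06d", seq_len(n))
  rates <- cfg$map_discrepancy_rates
  cats <- c(names(rates), "concordant")
  category <- sample(cats, n, replace = TRUE, prob = c(rates, 1 - sum(rates)))

  chrom_a <- grid$chrom; pos_a <- grid$pos
  chrom_b <- grid$chrom; pos_b <- grid$pos
  pick <- function(k) which(category == k)

  i <- pick("different_chromosomes")
  if (length(i)) {
    shift <- sample(cfg$n_autosomes - 1L, length(i), replace = TRUE)
    chrom_b[i] <- as.character((as.integer(chrom_a[i]) + shift - 1L) %% cfg$n_autosomes + 1L)
    pos_b[i] <- as.integer(floor(stats::runif(length(i), 1, cfg$chrom_length_bp)))
  }
  i <- pick("unknown_in_A"); chrom_a[i] <- NA; pos_a[i] <- NA
  i <- pick("unknown_in_B"); chrom_b[i] <- NA; pos_b[i] <- NA
  i <- pick("both_unknown")
  chrom_a[i] <- NA; pos_a[i] <- NA; chrom_b[i] <- NA; pos_b[i] <- NA
  i <- pick("shuffled")
  # swap with the next grid neighbour on the same chromosome in map B
  for (k in i) {
    if (k < n && chrom_b[k + 1L] %in% chrom_b[k] && category[k + 1L] == "concordant") {
      tmp <- pos_b[k]; pos_b[k] <- pos_b[k + 1L]; pos_b[k + 1L] <- tmp
    }
  }
  in_a <- category != "missing_from_A"
  in_b <- category != "missing_from_B"
  map_a <- snp_map(name[in_a], chrom_a[in_a], pos_a[in_a])
  map_b <- snp_map(name[in_b], chrom_b[in_b], pos_b[in_b])

  truth_cat <- category
  truth_cat[truth_cat %in% c("shuffled", "concordant")] <- "same_chromosome"
  list(map_a = map_a, map_b = map_b,
       truth = tibble::tibble(name = name, category = truth_cat),
       shuffled_markers = name[category == "shuffled"])
}

#' Simulate a refGene-style gene set around the planted regions
#'
#' Plants two genes inside every archetype (fully contained) and a
#' background gene well outside any archetype on each chromosome, recording
#' which region (if any) each gene sits in.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (a `gene_table`) and `placement` (tibble:
#'   gene_name, region_id or `"outside"`).
#' @export
simulate_genes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  arch <- cfg$cnvr_archetypes
  inside <- dplyr::bind_rows(lapply(seq_len(nrow(arch)), function(i) {
    len <- arch$end[i] - arch$start[i] + 1L
    w <- max(1000L, as.integer(len %/% 5L))
    s1 <- arch$start[i] + as.integer(len %/% 10L)
    s2 <- arch$start[i] + as.integer(len %/% 2L)
    tibble::tibble(
      gene_name = sprintf("GENE_%s_%d", arch$region_id[i], 1:2),
      chrom = arch$chrom[i],
      tx_start = c(s1, s2), tx_end = c(s1 + w, s2 + w),
      region_id = arch$region_id[i]
    )
  }))
  # background genes parked in the last Mb, away from every archetype
  outside <- tibble::tibble(
    gene_name = sprintf("BG_GENE_%02d", seq_len(cfg$n_autosomes)),
    chrom = as.character(seq_len(cfg$n_autosomes)),
    tx_start = as.integer(cfg$chrom_length_bp - 5e5),
    tx_end = as.integer(cfg$chrom_length_bp - 4e5),
    region_id = "outside"
  )
  all_genes <- dplyr::bind_rows(inside, outside)
  list(genes = gene_table(all_genes$gene_name, all_genes$chrom,
                          all_genes$tx_start, all_genes$tx_end, "+"),
       placement = all_genes[, c("gene_name", "region_id")])
}

#' Write a simulated cohort to disk in its native formats
#'
#' PennCNV rawcnv text, CNVPartition-style export, both SNP maps, the
#' refGene table, the QC table and a JSON truth manifest.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_penncnv_calls(sim$calls$penncnv, p("penncnv.rawcnv"))
  write_cnvpartition_calls(sim$calls$cnvpartition, p("cnvpartition.txt"))
  write_snp_map(sim$map_a, p("map_a.tsv"))
  write_snp_map(sim$map_b, p("map_b.tsv"))
  write_refgene(sim$genes, p("refgene.txt"))
  write_sample_qc(sim$qc, p("sample_qc.tsv"))
  truth <- sim$truth
  truth$fp_calls <- lapply(truth$fp_calls, as.data.frame)
  truth$long_artifacts <- lapply(truth$long_artifacts, as.data.frame)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns")
  files <- c(penncnv = p("penncnv.rawcnv"), cnvpartition = p("cnvpartition.txt"),
             map_a = p("map_a.tsv"), map_b = p("map_b.tsv"),
             refgene = p("refgene.txt"), qc = p("sample_qc.tsv"),
             truth = p("truth.json"))
  invisible(files)
}
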