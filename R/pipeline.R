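# End-to-end driver: clean -> summarize -> CNVR -> cross-caller comparison
# -> consensus -> gene annotation -> consensus genes -> manifest comparison,
# writing every table plus a run log. Each stage is an exported function;
# the driver only sequences them.

#' Pipeline configuration
#'
#' @param penncnv,cnvpartition Paths to call lists (either may be `NULL`;
#'   with a single caller the cross-caller comparison is skipped).
#' @param qc Path to a per-sample QC TSV, or `NULL` to skip sample QC.
#' @param refgene Path to a refGene-style table, or `NULL` to skip genes.
#' @param map_a,map_b Paths to SNP maps for the cross-assembly comparison,
#'   or `NULL` to skip it.
#' @param genome A [genome_build()] (required).
#' @param n_individuals Cohort size used for frequencies and the consensus
#'   threshold.
#' @param external_cnvr Optional path to an external CNVR BED/TSV pair (as
#'   written by [write_cnvr_bed()]) for database cross-validation.
#' @param clean A [clean_config()].
#' @param consensus_proportion Frequency threshold for consensus calling.
#' @param out_dir Output directory.
#' @param build Assembly label for parsed calls.
#' @param plots Emit the CNVR distribution map.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(penncnv = NULL, cnvpartition = NULL, qc = NULL,
                            refgene = NULL, map_a = NULL, map_b = NULL,
                            genome, n_individuals,
                            external_cnvr = NULL,
                            clean = clean_config(),
                            consensus_proportion = 0.05,
                            out_dir = "results", build = "unknown",
                            plots = TRUE) {
  stopifnot(inherits(genome, "genome_build"), n_individuals >= 1)
  for (f in c(penncnv, cnvpartition, qc, refgene, map_a, map_b, external_cnvr))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  structure(list(penncnv = penncnv, cnvpartition = cnvpartition, qc = qc,
                 refgene = refgene, map_a = map_a, map_b = map_b,
                 genome = genome, n_individuals = as.integer(n_individuals),
                 external_cnvr = external_cnvr, clean = clean,
                 consensus_proportion = consensus_proportion,
                 out_dir = out_dir, build = build, plots = plots),
            class = "pipeline_config")
}

write_tsv_out <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full post-calling pipeline
#'
#' Sequences every stage on the configured inputs and writes the report
#' bundle: cleaned calls, per-caller CNV summaries, CNVR tables and BEDs,
#' cross-caller comparison reports, the consensus CNVR set, gene annotation
#' and consensus genes, the manifest comparison, optional database
#' cross-validation, a CNVR distribution map, and `run_log.txt` recording
#' parameters and versions. The pipeline is deterministic: identical inputs
#' give identical tables.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of stage results, invisibly mirrored on disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("cnvrkit %s | run at %s",
                         as.character(utils::packageVersion("cnvrkit")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("consensus proportion: %g", cfg$consensus_proportion),
                 sprintf("n_individuals: %d", cfg$n_individuals))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  qc <- if (!is.null(cfg$qc)) read_sample_qc(cfg$qc)
  raw <- list()
  if (!is.null(cfg$penncnv))
    raw$penncnv <- stage("read", read_penncnv_calls(cfg$penncnv, cfg$build))
  if (!is.null(cfg$cnvpartition))
    raw$cnvpartition <- stage("read", read_cnvpartition_calls(cfg$cnvpartition, cfg$build))
  if (!length(raw)) stop("no caller inputs configured")

  cleaned <- lapply(raw, function(x) stage("clean", cnv_clean(x, qc, cfg$clean)))
  n_excluded <- nrow(cleaned[[1]]$excluded_samples)
  n_eff <- cfg$n_individuals - n_excluded
  log_lines <- c(log_lines, sprintf("samples excluded by QC: %d", n_excluded))

  summaries <- lapply(names(cleaned), function(k) {
    s <- stage("summarize", summarize_cnvs(cleaned[[k]]$calls, n_eff))
    write_tsv_out(s$per_state, cfg$out_dir, sprintf("cnv_summary_%s.tsv", k))
    s
  })
  names(summaries) <- names(cleaned)

  regions <- lapply(names(cleaned), function(k) {
    r <- stage("call_cnvr", call_cnvr(cleaned[[k]]$calls, source = k))
    write_cnvr_bed(r, file.path(cfg$out_dir, sprintf("cnvr_%s.bed", k)))
    r
  })
  names(regions) <- names(cleaned)
  rsum <- lapply(regions, function(r) stage("cnvr_summary", cnvr_summary(r, cfg$genome)))
  for (k in names(rsum))
    write_tsv_out(rsum[[k]]$per_type, cfg$out_dir, sprintf("cnvr_summary_%s.tsv", k))

  comparison <- NULL
  if (length(cleaned) >= 2L) {
    a <- cleaned[[1]]$calls; b <- cleaned[[2]]$calls
    comparison <- stage("compare", list(
      cnv_individual = compare_cnv(a, b, "individual"),
      cnv_population = compare_cnv(a, b, "population"),
      cnvr = compare_cnvr(regions[[1]], regions[[2]])
    ))
    write_tsv_out(dplyr::bind_rows(comparison$cnv_individual,
                                   comparison$cnv_population),
                  cfg$out_dir, "compare_cnv.tsv")
    write_tsv_out(comparison$cnvr$report, cfg$out_dir, "compare_cnvr.tsv")
  } else {
    log_lines <- c(log_lines, "single caller configured: cross-caller comparison skipped")
  }

  threshold_n <- consensus_threshold(n_eff, cfg$consensus_proportion)
  log_lines <- c(log_lines, sprintf("consensus threshold: >= %d carriers", threshold_n))
  consensus <- stage("consensus",
                     consensus_cnvrs(lapply(cleaned, `[[`, "calls"), threshold_n))
  write_cnvr_bed(consensus$regions, file.path(cfg$out_dir, "consensus_cnvr.bed"))
  write_cnvr_bed(consensus$union_regions, file.path(cfg$out_dir, "union_cnvr.bed"))

  gene_out <- NULL
  if (!is.null(cfg$refgene)) {
    genes <- read_refgene(cfg$refgene)
    pooled <- dplyr::bind_rows(lapply(cleaned, `[[`, "calls"))
    ann <- stage("annotate", annotate_genes(pooled, genes, n_eff))
    cons_genes <- consensus_genes(ann$per_gene, threshold_n)
    write_tsv_out(ann$per_gene, cfg$out_dir, "gene_frequency.tsv")
    write_tsv_out(cons_genes, cfg$out_dir, "consensus_genes.tsv")
    gene_out <- list(annotation = ann, consensus = cons_genes)
  }

  map_out <- NULL
  if (!is.null(cfg$map_a) && !is.null(cfg$map_b)) {
    ma <- read_snp_map(cfg$map_a); mb <- read_snp_map(cfg$map_b)
    map_out <- stage("map_compare", list(
      classification = classify_marker_pairs(ma, mb),
      density_a = snp_density(ma, cfg$genome),
      density_b = snp_density(mb, cfg$genome),
      concordance = position_concordance(ma, mb)
    ))
    write_tsv_out(map_out$classification$counts, cfg$out_dir, "map_categories.tsv")
    write_tsv_out(map_out$concordance$discordance, cfg$out_dir, "map_discordance.tsv")
  }

  db_out <- NULL
  if (!is.null(cfg$external_cnvr)) {
    ext <- read_cnvr_bed(cfg$external_cnvr)
    db_out <- stage("db_compare", compare_to_database(consensus$union_regions, ext))
    write_tsv_out(db_out, cfg$out_dir, "db_compare.tsv")
  }

  if (isTRUE(cfg$plots) && nrow(consensus$union_regions)) {
    render_cnvr_map(consensus$union_regions, consensus$regions, cfg$genome,
                    file.path(cfg$out_dir, "cnvr_map.png"))
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(cleaned = cleaned, summaries = summaries, regions = regions,
                 cnvr_summaries = rsum, comparison = comparison,
                 consensus = consensus, threshold_n = threshold_n,
                 genes = gene_out, map = map_out, database = db_out,
                 n_effective = n_eff))
}

#' Draw a CNVR distribution map
#'
#' One horizontal track per chromosome with region glyphs coloured by type;
#' consensus regions are underlined, and each chromosome is labelled with
#' its CNVR coverage percentage.
#'
#' @param regions Region tibble (the full set).
#' @param consensus_regions Subset to mark as consensus (may be empty).
#' @param genome A [genome_build()].
#' @param path Output PNG path (`NULL` returns the plot object only).
#' @return The ggplot object, invisibly.
#' @export
render_cnvr_map <- function(regions, consensus_regions, genome, path = NULL) {
  stopifnot(nrow(regions) > 0)
  chroms <- names(genome$chrom_lengths)
  cov <- cnvr_summary(regions, genome)$per_chrom
  lab <- sprintf("%s (%.1f%%)", chroms,
                 ifelse(is.na(cov$coverage_pct[match(chroms, cov$chrom)]), 0,
                        cov$coverage_pct[match(chroms, cov$chrom)]))
  ypos <- stats::setNames(rev(seq_along(chroms)), chroms)
  regions$y <- ypos[regions$chrom]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble::tibble(chrom = chroms, len = unname(genome$chrom_lengths),
                            y = unname(ypos)),
      ggplot2::aes(x = 0, xend = .data$len / 1e6, y = .data$y, yend = .data$y),
      linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                   fill = .data$type)) +
    ggplot2::scale_y_continuous(breaks = unname(ypos), labels = lab) +
    ggplot2::scale_fill_manual(values = c(gain = "#2c7fb8", loss = "#d95f0e",
                                          mixed = "#31a354")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "CNVR type") +
    ggplot2::theme_minimal(base_size = 9)
  if (nrow(consensus_regions)) {
    consensus_regions$y <- ypos[consensus_regions$chrom]
    p <- p + ggplot2::geom_segment(
      data = consensus_regions,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$y - 0.42, yend = .data$y - 0.42),
      colour = "purple", linewidth = 1.2)
  }
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 120)
  invisible(p)
}

#' Dot plot of marker positions between two manifests
#'
#' The classic per-chromosome diagnostic: concordant markers fall on the
#' diagonal, locally reordered markers sit just off it, and cross-
#' chromosome markers are drawn in a contrasting colour.
#'
#' @param concordance Result of [position_concordance()].
#' @param chrom Chromosome to plot.
#' @param path Optional output PNG path.
#' @return The ggplot object, invisibly.
#' @export
render_map_dotplot <- function(concordance, chrom, path = NULL) {
  d <- concordance$pairs[concordance$pairs$chrom == chrom, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_a / 1e6, y = .data$pos_b / 1e6)) +
    ggplot2::geom_point(size = 0.4, colour = "#2c7fb8") +
    ggplot2::labs(x = "map A position (Mb)", y = "map B position (Mb)",
                  title = paste("chromosome", chrom)) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 4, height = 4, dpi = 120)
  invisible(p)
}
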