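# Gene annotation of CNVs/CNVRs, per-gene carrier frequency, consensus
# genes, and name-based gene-set comparison across assemblies.

#' Annotate calls or regions with genes
#'
#' Emits one hit for every (gene, item) pair sharing at least one bp, then
#' aggregates per gene: how many items intersect the gene and — when the
#' items are per-sample calls — how many distinct samples carry one.
#' Per-gene frequency is the carrier percentage of the cohort. Counting
#' carriers per gene rather than per region matters because breakpoints
#' vary between samples, so a gene inside a frequent region can itself be
#' hit in far fewer samples.
#'
#' @param items A `cnv_calls` tibble or a region tibble from [call_cnvr()].
#' @param genes A `gene_table` on the same assembly.
#' @param cohort_size Number of individuals, for `frequency_pct`; `NA`
#'   frequencies when omitted.
#' @return A list with `hits` (gene_name, item_id, overlap_bp, sample_id if
#'   available) and `per_gene` (gene_name, chrom, n_cnvs, n_samples,
#'   frequency_pct), sorted by descending carrier count.
#' @export
annotate_genes <- function(items, genes, cohort_size = NULL) {
  is_calls <- inherits(items, "cnv_calls") || "sample_id" %in% names(items)
  item_id <- if ("region_id" %in% names(items)) items$region_id
             else sprintf("call_%d", seq_len(nrow(items)))
  g <- tibble::tibble(chrom = genes$chrom, start = genes$tx_start, end = genes$tx_end)
  pairs <- overlap_pairs(g, items)
  hits <- tibble::tibble(
    gene_name = genes$gene_name[pairs$a_row],
    item_id = item_id[pairs$b_row],
    overlap_bp = pairs$overlap_bp,
    sample_id = if (is_calls) items$sample_id[pairs$b_row] else NA_character_
  )
  per_gene <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(gene_name = genes$gene_name[pairs$a_row],
                     chrom = genes$chrom[pairs$a_row],
                     sample_id = hits$sample_id,
                     n_samples_item = if (!is_calls && "n_samples" %in% names(items))
                       items$n_samples[pairs$b_row] else NA_integer_),
      .data$gene_name, .data$chrom),
    n_cnvs = dplyr::n(),
    n_samples = if (is_calls) length(unique(.data$sample_id))
                else suppressWarnings(max(.data$n_samples_item)),
    .groups = "drop"
  )
  per_gene$frequency_pct <- if (!is.null(cohort_size))
    100 * per_gene$n_samples / cohort_size else NA_real_
  per_gene <- per_gene[order(-per_gene$n_samples, per_gene$gene_name), ]
  list(hits = hits, per_gene = per_gene)
}

#' Consensus genes by carrier-count threshold
#'
#' Keeps the genes carried by at least `threshold_n` distinct samples
#' (inclusive), sorted by descending frequency — the same rule that defines
#' consensus CNVRs, applied per gene.
#'
#' @param per_gene The `per_gene` table from [annotate_genes()].
#' @param threshold_n Carrier-count threshold, see [consensus_threshold()].
#' @return The passing subset of `per_gene`.
#' @export
consensus_genes <- function(per_gene, threshold_n) {
  keep <- per_gene$n_samples >= threshold_n
  out <- per_gene[keep, ]
  out[order(-out$n_samples, out$gene_name), ]
}

#' Compare consensus gene sets across assemblies by name
#'
#' Gene symbols are assumed stable across reference builds, so name-based
#' set algebra compares results whose coordinates cannot be compared
#' directly. Matching is case-insensitive; an optional synonym map (named
#' character vector, `name -> canonical`) harmonizes aliases first.
#'
#' @param genes_a,genes_b Character vectors of gene names.
#' @param synonyms Optional named character vector of synonym replacements.
#' @return A list with disjoint `shared`, `a_only`, `b_only` (in original
#'   casing from the first carrier) and `union_size`.
#' @export
compare_genes_across_builds <- function(genes_a, genes_b, synonyms = NULL) {
  canon <- function(x) {
    if (!is.null(synonyms)) {
      hit <- match(toupper(x), toupper(names(synonyms)))
      x[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
    }
    toupper(x)
  }
  ka <- unique(canon(genes_a)); kb <- unique(canon(genes_b))
  orig <- stats::setNames(c(genes_a, genes_b), canon(c(genes_a, genes_b)))
  orig <- orig[!duplicated(names(orig))]
  shared <- intersect(ka, kb)
  list(shared = unname(orig[shared]),
       a_only = unname(orig[setdiff(ka, kb)]),
       b_only = unname(orig[setdiff(kb, ka)]),
       union_size = length(union(ka, kb)))
}

#' Flag consensus genes not backed by a consensus region
#'
#' With per-sample calls a gene can in principle reach the carrier
#' threshold through calls split across several below-threshold regions
#' (breakpoints fragment the locus). This cross-check reports, for each
#' consensus gene, whether it intersects at least one region meeting the
#' same threshold.
#'
#' @param genes_passing `per_gene` rows that passed the threshold, with
#'   `chrom` column; needs `gene_table` coordinates via `gene_coords`.
#' @param gene_coords The `gene_table` the hits were computed from.
#' @param regions Region tibble from [call_cnvr()].
#' @param threshold_n The carrier threshold.
#' @return `genes_passing` with a logical `in_consensus_region` column.
#' @export
check_genes_in_consensus_regions <- function(genes_passing, gene_coords,
                                             regions, threshold_n) {
  strong <- regions[regions$n_samples >= threshold_n, ]
  gi <- match(genes_passing$gene_name, gene_coords$gene_name)
  g <- tibble::tibble(chrom = gene_coords$chrom[gi],
                      start = gene_coords$tx_start[gi],
                      end = gene_coords$tx_end[gi])
  pairs <- overlap_pairs(g, strong)
  genes_passing$in_consensus_region <- seq_len(nrow(genes_passing)) %in% pairs$a_row
  genes_passing
}
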