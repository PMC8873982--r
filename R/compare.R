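# Cross-caller and cross-list comparison: call-level overlap at individual
# and population scope, region-level overlap with union-length accounting,
# frequency-threshold consensus calling on pooled call sets, and
# database-style cross-validation.

# per-chromosome >=1bp overlap pairs between two interval tables;
# returns tibble of row indices into a and b plus the shared bp
overlap_pairs <- function(a, b) {
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr); ib <- which(b$chrom == chr)
    ra <- IRanges::IRanges(a$start[ia], a$end[ia])
    rb <- IRanges::IRanges(b$start[ib], b$end[ib])
    h <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    if (!length(h)) next
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ov <- pmin(a$end[ia][qi], b$end[ib][si]) - pmax(a$start[ia][qi], b$start[ib][si]) + 1L
    out[[chr]] <- tibble::tibble(a_row = ia[qi], b_row = ib[si], overlap_bp = ov)
  }
  if (!length(out))
    return(tibble::tibble(a_row = integer(), b_row = integer(), overlap_bp = integer()))
  dplyr::bind_rows(out)
}

# total bp covered by both lists: length of intersect(union A, union B)
overlap_union_length <- function(a, b) {
  total <- 0
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == chr], a$end[a$chrom == chr]))
    rb <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == chr], b$end[b$chrom == chr]))
    total <- total + sum(as.numeric(IRanges::width(IRanges::intersect(ra, rb))))
  }
  total
}

total_length <- function(x) sum(as.numeric(x$end - x$start + 1L))

#' Compare two CNV call lists
#'
#' A call in one list counts as overlapped when some call in the other list
#' shares at least one bp with it — and, at the individual level, comes from
#' the same sample. Population level ignores sample identity, so its
#' overlap percentage is always at least the individual-level one. Each call
#' counts once however many partners it overlaps; the same-state breakdown
#' asks whether any overlapping partner has the identical copy number.
#'
#' @param a,b `cnv_calls` tibbles on the same assembly.
#' @param level `"individual"` or `"population"`.
#' @return A tibble with one row per direction (`a_vs_b`, `b_vs_a`):
#'   `n_total`, `n_overlapped`, `pct_overlapped`, `n_same_state`,
#'   `n_different_state`.
#' @export
compare_cnv <- function(a, b, level = c("individual", "population")) {
  level <- match.arg(level)
  a <- validate_cnv_calls(a); b <- validate_cnv_calls(b)
  if (!nrow(a) || !nrow(b)) warning("empty call list in comparison")
  one_direction <- function(x, y, dir) {
    pairs <- overlap_pairs(x, y)
    if (level == "individual" && nrow(pairs))
      pairs <- pairs[x$sample_id[pairs$a_row] == y$sample_id[pairs$b_row], ]
    hit <- sort(unique(pairs$a_row))
    same <- unique(pairs$a_row[x$cn[pairs$a_row] == y$cn[pairs$b_row]])
    tibble::tibble(
      direction = dir, level = level, n_total = nrow(x),
      n_overlapped = length(hit),
      pct_overlapped = if (nrow(x)) proportion_pct(length(hit), nrow(x)) else NA_real_,
      n_same_state = length(same),
      n_different_state = length(hit) - length(same)
    )
  }
  dplyr::bind_rows(one_direction(a, b, "a_vs_b"), one_direction(b, a, "b_vs_a"))
}

#' Compare two CNVR lists
#'
#' Reports every >=1-bp intersecting region pair with the shared length and
#' its fraction of each region, plus a length report where the overlapped
#' length is the union of all pairwise intersections — shared bases are
#' never double counted, so the overlapped length can never exceed either
#' side's total length.
#'
#' @param a,b Region tibbles from [call_cnvr()] on the same assembly.
#' @return A list with `pairs` (tibble `a_id`, `b_id`, `overlap_bp`,
#'   `frac_a`, `frac_b`, `state_match`) and `report` (one-row tibble with
#'   per-side region counts, regions hit, hit percentages, the overlapped
#'   length in bp and its percentage of each side's total length).
#' @export
compare_cnvr <- function(a, b) {
  pairs <- overlap_pairs(a, b)
  len_a <- a$end - a$start + 1L
  len_b <- b$end - b$start + 1L
  pairs_out <- tibble::tibble(
    a_id = a$region_id[pairs$a_row],
    b_id = b$region_id[pairs$b_row],
    overlap_bp = pairs$overlap_bp,
    frac_a = pairs$overlap_bp / len_a[pairs$a_row],
    frac_b = pairs$overlap_bp / len_b[pairs$b_row],
    state_match = ifelse(a$type[pairs$a_row] == b$type[pairs$b_row],
                         "same", "different")
  )
  ov_len <- overlap_union_length(a, b)
  tot_a <- total_length(a); tot_b <- total_length(b)
  report <- tibble::tibble(
    n_a = nrow(a), n_a_hit = length(unique(pairs$a_row)),
    pct_a_hit = if (nrow(a)) proportion_pct(length(unique(pairs$a_row)), nrow(a)) else NA_real_,
    n_b = nrow(b), n_b_hit = length(unique(pairs$b_row)),
    pct_b_hit = if (nrow(b)) proportion_pct(length(unique(pairs$b_row)), nrow(b)) else NA_real_,
    overlap_length_bp = ov_len,
    pct_length_a = if (tot_a > 0) proportion_pct(ov_len, tot_a) else NA_real_,
    pct_length_b = if (tot_b > 0) proportion_pct(ov_len, tot_b) else NA_real_
  )
  list(pairs = pairs_out, report = report)
}

#' Sample-count threshold for consensus calling
#'
#' The consensus frequency rule keeps regions carried by at least a fixed
#' proportion of the cohort; the count threshold is the ceiling of the
#' smallest cohort size times that proportion (e.g. 393 samples at 5%
#' gives 19.65, so 20 carriers are required).
#'
#' @param sample_sizes Cohort sizes of the lists being pooled (all >= 1).
#' @param proportion Frequency threshold, default 0.05.
#' @return Integer carrier-count threshold.
#' @export
consensus_threshold <- function(sample_sizes, proportion = 0.05) {
  if (!length(sample_sizes)) stop("`sample_sizes` must be non-empty")
  stopifnot(all(sample_sizes >= 1), proportion > 0)
  as.integer(ceiling(min(sample_sizes) * proportion))
}

#' Call consensus CNVRs from pooled call lists
#'
#' Pools the call lists of two or more callers (on one assembly), merges
#' the pool into union-set CNVRs with [call_cnvr()], and keeps the regions
#' whose distinct-carrier count reaches `threshold_n`. A sample reported by
#' both callers at one locus counts once.
#'
#' @param call_lists A list of `cnv_calls` tibbles sharing one assembly.
#' @param threshold_n Carrier-count threshold (inclusive `>=`).
#' @param source Label for the union set.
#' @return A list of class `consensus_set`: `regions` (passing regions),
#'   `union_regions` (all union-set regions), `threshold_n`, `sources`.
#' @export
consensus_cnvrs <- function(call_lists, threshold_n, source = "union") {
  stopifnot(is.list(call_lists), length(call_lists) >= 1L)
  call_lists <- lapply(call_lists, validate_cnv_calls)
  builds <- unique(unlist(lapply(call_lists, function(x) unique(x$build))))
  if (length(builds) > 1L)
    stop("call lists are on different assemblies: ", paste(builds, collapse = ", "))
  pooled <- dplyr::bind_rows(call_lists)
  union_regions <- call_cnvr(pooled, source = source)
  keep <- union_regions$n_samples >= threshold_n
  structure(list(
    regions = union_regions[keep, ],
    union_regions = union_regions,
    threshold_n = as.integer(threshold_n),
    sources = unique(pooled$caller)
  ), class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("Consensus set: %d of %d union CNVRs with >= %d carriers (callers: %s)\n",
              nrow(x$regions), nrow(x$union_regions), x$threshold_n,
              paste(x$sources, collapse = ", ")))
  invisible(x)
}

#' Cross-validate a CNVR list against an external database list
#'
#' Counts the study regions that share >=1 bp with any external region, the
#' external regions hit, the study regions with no hit (candidate
#' population-specific regions), and the overlapped length (union
#' accounting) with its percentage of the study's total length.
#'
#' @param study,external Region tibbles in the same coordinates.
#' @return A one-row tibble report.
#' @export
compare_to_database <- function(study, external) {
  pairs <- overlap_pairs(study, external)
  ov_len <- overlap_union_length(study, external)
  tot <- total_length(study)
  tibble::tibble(
    n_study = nrow(study),
    n_study_hit = length(unique(pairs$a_row)),
    pct_study_hit = if (nrow(study)) proportion_pct(length(unique(pairs$a_row)), nrow(study)) else NA_real_,
    n_external_hit = length(unique(pairs$b_row)),
    n_study_specific = nrow(study) - length(unique(pairs$a_row)),
    overlap_length_bp = ov_len,
    pct_study_length = if (tot > 0) proportion_pct(ov_len, tot) else NA_real_
  )
}

#' Flag regions intersecting a known-artifact blacklist
#'
#' Marks study regions that share >=1 bp with any blacklist interval (e.g.
#' regions known to be assembly errors in the reference).
#'
#' @param study Region tibble.
#' @param blacklist Tibble with `chrom`, `start`, `end` and an id column
#'   (`region_id` or `id`).
#' @return The flagged subset of `study` with a `blacklist_id` column.
#' @export
flag_known_artifacts <- function(study, blacklist) {
  id_col <- intersect(c("region_id", "id"), names(blacklist))[1]
  if (is.na(id_col)) {
    blacklist$id <- sprintf("BL_%d", seq_len(nrow(blacklist)))
    id_col <- "id"
  }
  pairs <- overlap_pairs(study, blacklist)
  if (!nrow(pairs)) {
    out <- study[0, ]
    out$blacklist_id <- character()
    return(out)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(pairs, .data$a_row),
    blacklist_id = paste(blacklist[[id_col]][.data$b_row], collapse = ","),
    .groups = "drop"
  )
  out <- study[agg$a_row, ]
  out$blacklist_id <- agg$blacklist_id
  out
}
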