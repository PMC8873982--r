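# Population CNV regions: connected components of the >=1-bp interval
# overlap graph per chromosome, classified gain/loss/mixed, with
# distinct-sample frequencies and genome-coverage summaries.

#' Classify a set of member copy numbers
#'
#' A region is a gain when every member call is a duplication (cn > 2), a
#' loss when every member is a deletion (cn < 2), and mixed when it contains
#' at least one of each.
#'
#' @param cn Integer vector of member copy numbers (no 2s).
#' @return `"gain"`, `"loss"` or `"mixed"`.
#' @export
classify_cnv_type <- function(cn) {
  if (!length(cn)) stop("cannot classify an empty region")
  if (any(cn == 2L)) stop("diploid member (cn=2) is an impossible state")
  if (all(cn > 2L)) "gain" else if (all(cn < 2L)) "loss" else "mixed"
}

#' Merge CNV calls into CNV regions (CNVRs)
#'
#' Calls that share at least one bp are merged transitively: the regions are
#' the connected components of the per-chromosome interval overlap graph
#' (`A.start <= B.end` and `B.start <= A.end`). Calls that merely touch
#' end-to-start (gap of zero bases) are *not* merged. Each region records
#' its member count, the number of distinct carrier samples (the region's
#' population frequency numerator), and its gain/loss/mixed type.
#'
#' Region ids are `CNVR_<k>` in (chromosome, start) order.
#'
#' @param calls A cleaned `cnv_calls` tibble (single assembly).
#' @param source Label recorded on each region (caller or union-set name).
#' @return A tibble of regions (`region_id`, `chrom`, `start`, `end`,
#'   `length`, `type`, `n_calls`, `n_samples`, `source`) carrying an
#'   `assignment` attribute: an integer vector mapping each input call row
#'   to its region row.
#' @export
call_cnvr <- function(calls, source = "pooled") {
  calls <- validate_cnv_calls(calls)
  if (length(unique(calls$build)) > 1L)
    stop("calls span multiple assemblies: ",
         paste(unique(calls$build), collapse = ", "))
  if (!nrow(calls)) {
    out <- tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(), length = integer(),
                          type = character(), n_calls = integer(),
                          n_samples = integer(), source = character())
    attr(out, "assignment") <- integer()
    return(out)
  }
  assignment <- integer(nrow(calls))
  pieces <- list()
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr)
    ir <- IRanges::IRanges(calls$start[idx], calls$end[idx])
    # min.gapwidth = 0: only true >=1-bp overlaps merge; adjacency splits
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    member_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    pieces[[chr]] <- tibble::tibble(
      chrom = chr,
      start = IRanges::start(red), end = IRanges::end(red),
      type = vapply(seq_along(red), function(r)
        classify_cnv_type(calls$cn[idx][member_of == r]), ""),
      n_calls = as.integer(tabulate(member_of, length(red))),
      n_samples = vapply(seq_along(red), function(r)
        length(unique(calls$sample_id[idx][member_of == r])), 0L)
    )
    pieces[[chr]]$.idx <- lapply(seq_along(red), function(r) idx[member_of == r])
  }
  regions <- dplyr::bind_rows(pieces)
  ord <- order(suppressWarnings(as.numeric(regions$chrom)), regions$chrom, regions$start)
  regions <- regions[ord, ]
  for (r in seq_len(nrow(regions))) assignment[regions$.idx[[r]]] <- r
  regions$.idx <- NULL
  regions$region_id <- sprintf("CNVR_%d", seq_len(nrow(regions)))
  regions$length <- regions$end - regions$start + 1L
  regions$source <- source
  regions <- regions[, c("region_id", "chrom", "start", "end", "length",
                         "type", "n_calls", "n_samples", "source")]
  attr(regions, "assignment") <- assignment
  regions
}

#' Summarize a CNVR set
#'
#' Per-type counts and length statistics, the total span, and genome
#' coverage as a percentage of the build's autosome length; also emits
#' per-chromosome coverage for distribution maps.
#'
#' @param regions A region tibble from [call_cnvr()].
#' @param genome A [genome_build()] supplying chromosome lengths.
#' @return A list of class `cnvr_summary` with `per_type`, `total_count`,
#'   `total_length_bp`, `genome_coverage_pct` and `per_chrom`.
#' @export
cnvr_summary <- function(regions, genome) {
  stopifnot(inherits(genome, "genome_build"))
  missing <- setdiff(unique(regions$chrom), names(genome$chrom_lengths))
  if (length(missing))
    stop("region chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  glen <- genome_length(genome)
  per_type <- dplyr::summarise(
    dplyr::group_by(regions, .data$type),
    n = dplyr::n(),
    mean_length = mean(.data$length),
    min_length = min(.data$length),
    max_length = max(.data$length),
    total_length = sum(as.numeric(.data$length)),
    .groups = "drop"
  )
  per_chrom <- dplyr::summarise(
    dplyr::group_by(regions, .data$chrom),
    n = dplyr::n(),
    total_length = sum(as.numeric(.data$length)),
    .groups = "drop"
  )
  per_chrom$chrom_length <- genome$chrom_lengths[per_chrom$chrom]
  per_chrom$coverage_pct <- 100 * per_chrom$total_length / per_chrom$chrom_length
  total_len <- sum(as.numeric(regions$length))
  structure(list(
    per_type = per_type,
    total_count = nrow(regions),
    total_length_bp = total_len,
    genome_coverage_pct = 100 * total_len / glen,
    per_chrom = per_chrom
  ), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNVR summary: %d regions, %s bp total (%.2f%% genome coverage)\n",
              x$total_count, format(x$total_length_bp, big.mark = ","),
              x$genome_coverage_pct))
  print(x$per_type)
  invisible(x)
}
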