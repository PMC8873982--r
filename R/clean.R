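# Post-calling QC: per-sample signal-quality exclusion, gap-merging of
# adjacent same-state calls, and a hard length cap, followed by the
# per-state summary used in cohort reports.

#' Cleaning configuration
#'
#' Thresholds for the standard post-calling filters. All QC comparisons are
#' strict inequalities: a sample sitting exactly on a threshold is kept.
#'
#' @param drop_length_mb Calls longer than this many Mb are discarded
#'   (default 5, strict `>`).
#' @param merge_fraction Adjacent same-state calls are merged when the gap is
#'   less than this fraction of the merged span (default 0.2).
#' @param lrr_sd_max Max allowed standard deviation of the Log R Ratio (0.30).
#' @param baf_drift_max Max allowed B-allele-frequency drift (0.005).
#' @param wave_factor_abs_max Max allowed |wave factor| (0.1).
#' @param merge_denominator `"span"` uses the full span from the first start
#'   to the second end (two calls plus the gap); `"lengths"` uses the summed
#'   call lengths only.
#' @return A list of class `clean_config`.
#' @export
clean_config <- function(drop_length_mb = 5, merge_fraction = 0.2,
                         lrr_sd_max = 0.30, baf_drift_max = 0.005,
                         wave_factor_abs_max = 0.1,
                         merge_denominator = c("span", "lengths")) {
  merge_denominator <- match.arg(merge_denominator)
  stopifnot(drop_length_mb > 0, merge_fraction > 0, merge_fraction < 1,
            lrr_sd_max > 0, baf_drift_max > 0, wave_factor_abs_max > 0)
  structure(list(drop_length_mb = drop_length_mb,
                 merge_fraction = merge_fraction,
                 lrr_sd_max = lrr_sd_max,
                 baf_drift_max = baf_drift_max,
                 wave_factor_abs_max = wave_factor_abs_max,
                 merge_denominator = merge_denominator),
            class = "clean_config")
}

#' Exclude samples with poor signal quality
#'
#' A sample is excluded when its LRR standard deviation, BAF drift or
#' absolute wave factor exceeds (strictly) the configured maximum; all
#' triggered reasons are reported per sample.
#'
#' @param qc A [sample_qc()] tibble, one row per sample.
#' @param cfg A [clean_config()].
#' @return A list with `kept` (character vector of sample ids) and
#'   `excluded` (tibble of sample_id and comma-separated reasons).
#' @export
filter_samples_by_qc <- function(qc, cfg = clean_config()) {
  stopifnot(inherits(qc, "sample_qc"))
  reasons <- mapply(function(sd, drift, wave) {
    r <- c(if (sd > cfg$lrr_sd_max) "LRR_SD",
           if (drift > cfg$baf_drift_max) "BAF_DRIFT",
           if (abs(wave) > cfg$wave_factor_abs_max) "WAVE_FACTOR")
    paste(r, collapse = ",")
  }, qc$lrr_sd, qc$baf_drift, qc$wave_factor)
  bad <- nzchar(reasons)
  list(kept = qc$sample_id[!bad],
       excluded = tibble::tibble(sample_id = qc$sample_id[bad],
                                 reasons = reasons[bad]))
}

# merge one (sample, chrom, cn) group, already sorted by start; left-to-right
# sweep repeated to a fixed point
merge_group <- function(g, fraction, denominator) {
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(g)) {
      a <- g[i, ]; b <- g[i + 1L, ]
      gap <- b$start - a$end - 1L
      if (gap < 0L) {
        warning("overlapping same-state calls within one sample merged unconditionally")
        do_merge <- TRUE
      } else {
        den <- if (denominator == "span") (max(a$end, b$end) - a$start + 1L)
               else (cnv_length(a) + cnv_length(b))
        do_merge <- (gap / den) < fraction
      }
      if (do_merge) {
        g$end[i] <- max(a$end, b$end)
        g$n_snp[i] <- a$n_snp + b$n_snp
        g$conf[i] <- suppressWarnings(min(a$conf, b$conf, na.rm = TRUE))
        if (!is.finite(g$conf[i])) g$conf[i] <- NA_real_
        g <- g[-(i + 1L), ]
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!changed) return(g)
  }
}

#' Merge adjacent same-state calls separated by a small gap
#'
#' Within each (sample, chromosome, copy-number, caller) group, two
#' neighbouring calls are combined when the gap between them is less than
#' `fraction` of the total length of the merged result; the sweep runs
#' left-to-right and repeats until no further merge applies, so the result
#' is a fixed point. Merged calls span both members, probe counts are
#' summed, and the confidence is the minimum of the members.
#'
#' @param calls A `cnv_calls` tibble.
#' @param fraction Gap-fraction threshold (strict `<`), default 0.2.
#' @param denominator See [clean_config()]; default `"span"`.
#' @return A `cnv_calls` tibble with merged records.
#' @export
merge_adjacent_calls <- function(calls, fraction = 0.2,
                                 denominator = c("span", "lengths")) {
  denominator <- match.arg(denominator)
  calls <- validate_cnv_calls(calls)
  if (!nrow(calls)) return(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$cn, calls$caller, sep = "\r")
  parts <- split(seq_len(nrow(calls)), key)
  out <- lapply(parts, function(idx) {
    g <- calls[idx[order(calls$start[idx])], ]
    merge_group(g, fraction, denominator)
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$sample_id, .data$chrom, .data$start)
  validate_cnv_calls(res)
}

#' Discard over-long calls
#'
#' Drops calls strictly longer than `drop_length_mb` megabases; a call of
#' exactly that length is kept. Such very long calls on array data are
#' usually chromosome-scale artifacts rather than real variants.
#'
#' @param calls A `cnv_calls` tibble.
#' @param drop_length_mb Length cap in Mb (default 5).
#' @return A list with `kept` and `dropped` call tibbles (a partition of the
#'   input).
#' @export
drop_long_cnvs <- function(calls, drop_length_mb = 5) {
  calls <- validate_cnv_calls(calls)
  too_long <- cnv_length(calls) > drop_length_mb * 1e6
  list(kept = calls[!too_long, ], dropped = calls[too_long, ])
}

#' Clean a raw call list
#'
#' Standard post-calling sequence: drop calls from QC-failing samples (when
#' a QC table is supplied), gap-merge adjacent same-state calls (PennCNV
#' lists only, by default — the CNVPartition segmentation does not emit the
#' fragmented runs the merge is meant to heal), then discard over-long
#' calls.
#'
#' @param calls A `cnv_calls` tibble.
#' @param qc Optional [sample_qc()] tibble.
#' @param cfg A [clean_config()].
#' @param merge_callers Callers whose calls are gap-merged.
#' @return A list with `calls` (cleaned), `dropped_long`, `excluded_samples`.
#' @export
cnv_clean <- function(calls, qc = NULL, cfg = clean_config(),
                      merge_callers = "penncnv") {
  calls <- validate_cnv_calls(calls)
  excluded <- tibble::tibble(sample_id = character(), reasons = character())
  if (!is.null(qc)) {
    keep <- filter_samples_by_qc(qc, cfg)
    excluded <- keep$excluded
    calls <- calls[!(calls$sample_id %in% excluded$sample_id), ]
  }
  to_merge <- calls$caller %in% merge_callers
  merged <- if (any(to_merge))
    merge_adjacent_calls(calls[to_merge, ], cfg$merge_fraction, cfg$merge_denominator)
  else calls[0, ]
  calls <- dplyr::bind_rows(merged, calls[!to_merge, ])
  lenfilter <- drop_long_cnvs(calls, cfg$drop_length_mb)
  list(calls = dplyr::arrange(lenfilter$kept, .data$sample_id, .data$chrom, .data$start),
       dropped_long = lenfilter$dropped,
       excluded_samples = excluded)
}

#' Report-style rounding helpers
#'
#' Printed tables round half away from zero (so 19.65% of 100 prints as
#' 19.7, and a mean of 9.5005 prints as 9.50), which differs from R's
#' banker's rounding. `proportion_pct()` is the percentage `100 * n / d`
#' rounded that way, the form every overlap and frequency report uses.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @param n,d Numerator and (positive) denominator.
#' @export
proportion_pct <- function(n, d, digits = 1) {
  stopifnot(d > 0)
  round_half_up(100 * n / d, digits)
}

#' Summarize a cleaned call list
#'
#' Per-copy-number counts and length statistics, the mean number of calls
#' per individual, and counts per length class — the cohort-description
#' table reported alongside a CNV study.
#'
#' @param calls A cleaned `cnv_calls` tibble.
#' @param n_individuals Number of individuals the calls were drawn from.
#' @return A list of class `cnv_summary` with `n_individuals`, `n_cnvs`,
#'   `cnvs_per_individual` (unrounded; reports round to 2 dp), `per_state`
#'   (tibble: cn, n, mean/min/max length) and `length_bins`.
#' @export
summarize_cnvs <- function(calls, n_individuals) {
  calls <- validate_cnv_calls(calls)
  if (n_individuals <= 0) stop("`n_individuals` must be positive")
  len <- cnv_length(calls)
  per_state <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cn = calls$cn, len = len), .data$cn),
    n = dplyr::n(),
    mean_length = mean(.data$len),
    min_length = min(.data$len),
    max_length = max(.data$len),
    .groups = "drop"
  )
  bins <- cut(len, c(0, 5e4, 1e5, 5e5, 1e6, Inf),
              labels = c("<50kb", "50-100kb", "100-500kb", "0.5-1Mb", ">1Mb"))
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_cnvs = nrow(calls),
    cnvs_per_individual = nrow(calls) / n_individuals,
    per_state = per_state,
    length_bins = tibble::as_tibble(as.data.frame(table(bin = bins),
                                                  responseName = "n"))
  ), class = "cnv_summary")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat(sprintf("CNV summary: %d calls in %d individuals (%.2f per individual)\n",
              x$n_cnvs, x$n_individuals,
              round_half_up(x$cnvs_per_individual, 2)))
  print(x$per_state)
  invisible(x)
}
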