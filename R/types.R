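# Domain containers. Calls, markers, genes and regions are plain tibbles with
# a fixed column contract; constructors validate the invariants once so the
# downstream stages can assume them.

#' Describe a genome assembly build
#'
#' A build is a named set of chromosome lengths plus the number of autosomes
#' considered for analysis. It supplies the denominator for genome-coverage
#' statistics and the coordinate bounds for the simulator.
#'
#' @param name Short assembly label, e.g. `"ARS"` or `"UMD"`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names are chromosome labels without any `"chr"` prefix.
#' @param n_autosomes Number of autosomes (defaults to all chromosomes given).
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(name, chrom_lengths, n_autosomes = length(chrom_lengths)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("`chrom_lengths` must be named by chromosome label")
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome labels must be unique")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  n_autosomes <- as.integer(n_autosomes)
  if (is.na(n_autosomes) || n_autosomes < 1L) stop("`n_autosomes` must be >= 1")
  structure(
    list(name = name, chrom_lengths = chrom_lengths, n_autosomes = n_autosomes),
    class = "genome_build"
  )
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s: %d chromosomes (%d autosomes), %.1f Mb total\n",
              x$name, length(x$chrom_lengths), x$n_autosomes,
              sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

#' Total genome length of a build
#'
#' @param build A [genome_build()].
#' @param autosomes_only Restrict to the first `n_autosomes` chromosomes.
#' @return Length in bp.
#' @export
genome_length <- function(build, autosomes_only = TRUE) {
  stopifnot(inherits(build, "genome_build"))
  len <- build$chrom_lengths
  if (autosomes_only) len <- len[seq_len(min(build$n_autosomes, length(len)))]
  sum(len)
}

#' Read a genome build from a two-column chromosome-length table
#'
#' @param path TSV with columns chromosome label and length in bp (no header).
#' @param name Assembly label.
#' @param n_autosomes Number of autosomes; default all rows.
#' @return A [genome_build()].
#' @export
read_genome_file <- function(path, name = "genome", n_autosomes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  lens <- stats::setNames(df$length, df$chrom)
  genome_build(name, lens, n_autosomes %||% length(lens))
}

#' Construct a table of CNV calls
#'
#' One row per CNV event in one sample. Coordinates are 1-based closed
#' intervals (the PennCNV convention); `cn` is the integer copy number and
#' must be one of 0, 1, 3, 4 — a diploid state is not a variant.
#'
#' @param sample_id,chrom,start,end,cn Core call fields (vectors recycled to
#'   common length).
#' @param n_snp Supporting probe count (>= 1).
#' @param conf Caller confidence score (caller-specific scale; `NA` allowed).
#' @param caller `"penncnv"` or `"cnvpartition"`.
#' @param build Assembly label the coordinates refer to.
#' @return A tibble of class `cnv_calls` with those nine columns.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cn,
                      n_snp = 1L, conf = NA_real_,
                      caller = "penncnv", build = "sim") {
  df <- tibble::tibble(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    cn = as.integer(cn),
    n_snp = as.integer(n_snp),
    conf = as.numeric(conf),
    caller = as.character(caller),
    build = as.character(build)
  )
  validate_cnv_calls(df)
}

#' Validate a CNV call table
#'
#' Checks the column contract and the call invariants (`start <= end`,
#' `cn` in \{0, 1, 3, 4\}, `n_snp >= 1`). Returns the table with class
#' `cnv_calls` attached, or aborts naming the offending rows.
#'
#' @param df A data frame with the [cnv_calls()] columns.
#' @return The validated tibble.
#' @export
validate_cnv_calls <- function(df) {
  required <- c("sample_id", "chrom", "start", "end", "cn",
                "n_snp", "conf", "caller", "build")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("call table is missing columns: ", paste(missing, collapse = ", "))
  df <- tibble::as_tibble(df)[required]
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("start > end at rows: ", paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!(df$cn %in% c(0L, 1L, 3L, 4L)))
  if (length(bad))
    stop("copy number outside {0,1,3,4} at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(df$n_snp < 1L)
  if (length(bad))
    stop("n_snp < 1 at rows: ", paste(utils::head(bad, 10L), collapse = ", "))
  class(df) <- unique(c("cnv_calls", class(df)))
  df
}

#' Length of each call in bp (closed-interval arithmetic)
#'
#' @param calls A `cnv_calls` or CNVR tibble with `start`/`end` columns.
#' @return Integer vector `end - start + 1`.
#' @export
cnv_length <- function(calls) calls$end - calls$start + 1L

#' Construct a SNP map (marker manifest) table
#'
#' Markers with no assigned position carry `NA` in both `chrom` and `pos`;
#' the two are jointly missing by construction.
#'
#' @param name Marker identifiers (unique, non-empty).
#' @param chrom Chromosome labels; `NA` for unplaced markers.
#' @param pos 1-based positions; `NA` for unplaced markers.
#' @return A tibble of class `snp_map`.
#' @export
snp_map <- function(name, chrom, pos) {
  df <- tibble::tibble(name = as.character(name),
                       chrom = as.character(chrom),
                       pos = as.integer(pos))
  # unknown is a joint state: either coordinate missing blanks both
  unk <- is.na(df$chrom) | is.na(df$pos)
  df$chrom[unk] <- NA_character_
  df$pos[unk] <- NA_integer_
  if (any(!nzchar(df$name) | is.na(df$name))) stop("marker names must be non-empty")
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup))
    stop("duplicate marker names: ", paste(utils::head(dup, 10L), collapse = ", "))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("known positions must be >= 1")
  class(df) <- unique(c("snp_map", class(df)))
  df
}

#' Construct a gene interval table
#'
#' @param gene_name Gene symbols (non-empty).
#' @param chrom Chromosome labels.
#' @param tx_start,tx_end Transcript span in bp, `tx_start < tx_end`.
#' @param strand `"+"` or `"-"`.
#' @return A tibble of class `gene_table`.
#' @export
gene_table <- function(gene_name, chrom, tx_start, tx_end, strand = "+") {
  df <- tibble::tibble(gene_name = as.character(gene_name),
                       chrom = as.character(chrom),
                       tx_start = as.integer(tx_start),
                       tx_end = as.integer(tx_end),
                       strand = as.character(strand))
  if (any(!nzchar(df$gene_name))) stop("gene names must be non-empty")
  bad <- which(df$tx_start >= df$tx_end)
  if (length(bad))
    stop("tx_start >= tx_end at rows: ", paste(utils::head(bad, 10L), collapse = ", "))
  class(df) <- unique(c("gene_table", class(df)))
  df
}

#' Per-sample signal-quality records
#'
#' Holds the PennCNV-style per-sample statistics used for cohort QC: the
#' standard deviation of the Log R Ratio, the B-allele-frequency drift and
#' the (signed) genomic wave factor.
#'
#' @param sample_id Sample labels (unique).
#' @param lrr_sd,baf_drift,wave_factor Per-sample statistics.
#' @return A tibble of class `sample_qc`.
#' @export
sample_qc <- function(sample_id, lrr_sd, baf_drift, wave_factor) {
  df <- tibble::tibble(sample_id = as.character(sample_id),
                       lrr_sd = as.numeric(lrr_sd),
                       baf_drift = as.numeric(baf_drift),
                       wave_factor = as.numeric(wave_factor))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample ids in QC table: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  if (any(df$lrr_sd < 0) || any(df$baf_drift < 0))
    stop("lrr_sd and baf_drift must be >= 0")
  class(df) <- unique(c("sample_qc", class(df)))
  df
}

# strip a leading "chr"/"Chr" prefix from chromosome labels
normalize_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
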