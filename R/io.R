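# Readers and writers for the external formats the pipeline touches:
# PennCNV rawcnv text, CNVPartition/GenomeStudio tab-separated exports,
# 3-column SNP maps, UCSC refGene tables and BED6 region exports. Every
# writer has a matching reader and write-then-read is the identity.

# state token PennCNV prints for each copy number
.penncnv_state <- c(`0` = "state1", `1` = "state2", `3` = "state5", `4` = "state6")

#' Read a PennCNV rawcnv call list
#'
#' Parses the standard PennCNV output layout, one call per line:
#' `chr1:1000-1999  numsnp=5  length=1,000  state2,cn=1  <sample>
#' startsnp=... endsnp=... conf=...`. Chromosome labels are normalized by
#' stripping any `chr` prefix; the printed `length` field is cross-checked
#' against `end - start + 1` and a mismatch raises a warning. Lines with
#' `cn=2` are rejected and reported, never kept.
#'
#' @param path Path to a rawcnv file.
#' @param build Assembly label to stamp on the calls.
#' @return A `cnv_calls` tibble with `caller = "penncnv"`.
#' @export
read_penncnv_calls <- function(path, build = "unknown") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("no CNV calls in ", path)
    return(cnv_calls(character(), character(), integer(), integer(),
                     integer(), caller = "penncnv", build = build))
  }
  m <- regmatches(lines, regexec(
    "^(\\S+):([0-9,]+)-([0-9,]+)\\s+numsnp=([0-9,]+)\\s+length=([0-9,]+)\\s+state[0-9]+,cn=([0-9]+)\\s+(\\S+)",
    lines))
  bad <- which(lengths(m) == 0L)
  if (length(bad))
    stop("malformed PennCNV line(s): ", paste(utils::head(bad, 10L), collapse = ", "),
         " in ", path)
  f <- function(i) vapply(m, `[[`, "", i + 1L)  # group i (element 1 is the full match)
  denum <- function(x) as.integer(gsub(",", "", x))
  cm <- regmatches(lines, regexec("conf=(-?[0-9.]+)", lines))
  conf_all <- rep(NA_real_, length(lines))
  has_conf <- lengths(cm) > 0L
  conf_all[has_conf] <- as.numeric(vapply(cm[has_conf], `[[`, "", 2L))
  cn <- as.integer(f(6))
  keep <- cn != 2L
  if (any(!keep)) warning(sum(!keep), " record(s) with cn=2 rejected")
  calls <- cnv_calls(
    sample_id = f(7)[keep],
    chrom = normalize_chrom(f(1))[keep],
    start = denum(f(2))[keep], end = denum(f(3))[keep], cn = cn[keep],
    n_snp = denum(f(4))[keep],
    conf = conf_all[keep],
    caller = "penncnv", build = build
  )
  printed_len <- denum(f(5))[keep]
  off <- which(printed_len != cnv_length(calls))
  if (length(off))
    warning("printed length disagrees with end-start+1 on ", length(off), " line(s)")
  calls
}

#' Write calls in PennCNV rawcnv layout
#'
#' @param calls A `cnv_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_penncnv_calls <- function(calls, path) {
  calls <- validate_cnv_calls(calls)
  state <- .penncnv_state[as.character(calls$cn)]
  conf <- ifelse(is.na(calls$conf), "", sprintf(" conf=%g", calls$conf))
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%d %s,cn=%d %s startsnp=snp_s endsnp=snp_e%s",
                   calls$chrom, calls$start, calls$end, calls$n_snp,
                   cnv_length(calls), state, calls$cn, calls$sample_id, conf)
  writeLines(lines, path)
  invisible(path)
}

#' Default GenomeStudio CNV-export column names
#'
#' The exact header varies with the GenomeStudio version, so the mapping is
#' a function argument; override individual entries to match an export.
#'
#' @return Named list mapping logical fields to column names.
#' @export
cnvpartition_columns <- function() {
  list(sample = "Sample ID", chrom = "Chr", start = "Start", end = "End",
       cn = "Value", conf = "Confidence", n_snp = "Num SNPs")
}

#' Read a CNVPartition/GenomeStudio CNV export
#'
#' Tab-separated table with a header row. Rows whose confidence falls below
#' `conf_floor` (the CNVPartition default of 35) are excluded; rows with a
#' diploid value are rejected and reported.
#'
#' @param path Path to the export.
#' @param build Assembly label.
#' @param conf_floor Minimum confidence kept (strict `<` excludes).
#' @param columns Column-name mapping, see [cnvpartition_columns()].
#' @return A `cnv_calls` tibble with `caller = "cnvpartition"`.
#' @export
read_cnvpartition_calls <- function(path, build = "unknown", conf_floor = 35,
                                    columns = cnvpartition_columns()) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- unlist(columns[c("sample", "chrom", "start", "end", "cn", "conf")])
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CNVPartition export is missing column(s): ",
         paste(missing, collapse = ", "))
  n_snp <- if (columns$n_snp %in% names(df)) as.integer(df[[columns$n_snp]]) else 1L
  cn <- as.integer(df[[columns$cn]])
  conf <- as.numeric(df[[columns$conf]])
  if (any(cn == 2L, na.rm = TRUE)) {
    warning(sum(cn == 2L), " diploid (cn=2) row(s) rejected")
  }
  keep <- cn != 2L & conf >= conf_floor
  calls <- cnv_calls(
    sample_id = df[[columns$sample]][keep],
    chrom = normalize_chrom(df[[columns$chrom]][keep]),
    start = as.integer(df[[columns$start]][keep]),
    end = as.integer(df[[columns$end]][keep]),
    cn = cn[keep],
    n_snp = if (length(n_snp) > 1L) n_snp[keep] else n_snp,
    conf = conf[keep],
    caller = "cnvpartition", build = build
  )
  calls
}

#' Write calls as a CNVPartition/GenomeStudio-style export
#'
#' @inheritParams write_penncnv_calls
#' @param columns Column-name mapping.
#' @return `path`, invisibly.
#' @export
write_cnvpartition_calls <- function(calls, path, columns = cnvpartition_columns()) {
  calls <- validate_cnv_calls(calls)
  out <- data.frame(calls$sample_id, calls$chrom, calls$start, calls$end,
                    calls$cn, ifelse(is.na(calls$conf), 100, calls$conf),
                    calls$n_snp, check.names = FALSE)
  names(out) <- unlist(columns[c("sample", "chrom", "start", "end", "cn", "conf", "n_snp")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a three-column SNP map
#'
#' Expects columns SNP name, chromosome, position (TSV or CSV, detected from
#' the first line; header detected or forced). Chromosome labels `"0"`,
#' `""`, `"NA"` or starting with `"Un"`, and positions `<= 0`, mark a marker
#' as unplaced; these sentinels are configurable.
#'
#' @param path Path to the map file.
#' @param header `"auto"`, `TRUE` or `FALSE`.
#' @param unknown_chroms Chromosome sentinels meaning "unplaced".
#' @return An `snp_map` tibble.
#' @export
read_snp_map <- function(path, header = "auto",
                         unknown_chroms = c("0", "", "NA")) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (identical(header, "auto")) {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- length(fields) >= 3L && is.na(suppressWarnings(as.numeric(fields[3])))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", quote = "",
                          col.names = c("name", "chrom", "pos"),
                          comment.char = "")
  chrom <- normalize_chrom(df$chrom)
  pos <- suppressWarnings(as.integer(df$pos))
  unk <- is.na(chrom) | chrom %in% unknown_chroms | startsWith(chrom, "Un") |
    is.na(pos) | pos <= 0L
  snp_map(df$name, ifelse(unk, NA_character_, chrom), ifelse(unk, NA_integer_, pos))
}

#' Write a SNP map as three-column TSV
#'
#' Unplaced markers are written with chromosome and position `0`.
#'
#' @param map An `snp_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_map <- function(map, path) {
  out <- data.frame(Name = map$name,
                    Chromosome = ifelse(is.na(map$chrom), "0", map$chrom),
                    Position = ifelse(is.na(map$pos), 0L, map$pos))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC refGene-style annotation table
#'
#' Column positions follow the UCSC refGene dump (bin, name, chrom, strand,
#' txStart, txEnd, ..., name2) and are configurable. Multiple transcript rows
#' of the same gene on the same chromosome are collapsed to the union
#' interval; rows with `txStart >= txEnd` are rejected with a warning.
#'
#' @param path Path to the table (TSV, no header).
#' @param cols 1-based column indices for chrom, strand, txStart, txEnd and
#'   gene symbol.
#' @return A `gene_table` tibble, one row per (gene, chromosome).
#' @export
read_refgene <- function(path,
                         cols = c(chrom = 3L, strand = 4L, tx_start = 5L,
                                  tx_end = 6L, gene = 13L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(gene_table(character(), character(), integer(), integer(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pick <- function(i) vapply(parts, function(p) p[[i]], "")
  df <- tibble::tibble(
    gene_name = pick(cols[["gene"]]),
    chrom = normalize_chrom(pick(cols[["chrom"]])),
    tx_start = as.integer(pick(cols[["tx_start"]])),
    tx_end = as.integer(pick(cols[["tx_end"]])),
    strand = pick(cols[["strand"]])
  )
  bad <- df$tx_start >= df$tx_end
  if (any(bad)) {
    warning(sum(bad), " refGene row(s) with txStart >= txEnd rejected")
    df <- df[!bad, ]
  }
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$gene_name, .data$chrom),
    tx_start = min(.data$tx_start), tx_end = max(.data$tx_end),
    strand = .data$strand[1], .groups = "drop"
  )
  df <- dplyr::arrange(df, .data$chrom, .data$tx_start)
  gene_table(df$gene_name, df$chrom, df$tx_start, df$tx_end, df$strand)
}

#' Write a gene table in refGene column layout
#'
#' @param genes A `gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refgene <- function(genes, path) {
  n <- nrow(genes)
  out <- data.frame(
    bin = rep(0L, n), name = paste0("TX_", seq_len(max(n, 0L))),
    chrom = genes$chrom, strand = genes$strand,
    txStart = genes$tx_start, txEnd = genes$tx_end,
    cdsStart = genes$tx_start, cdsEnd = genes$tx_end,
    exonCount = 1L, exonStarts = genes$tx_start, exonEnds = genes$tx_end,
    score = 0L, name2 = genes$gene_name
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write per-sample QC tables
#'
#' Plain TSV with columns sample_id, lrr_sd, baf_drift, wave_factor.
#'
#' @param path File path.
#' @return [read_sample_qc()] returns a `sample_qc` tibble.
#' @export
read_sample_qc <- function(path) {
  df <- utils::read.delim(path)
  sample_qc(df$sample_id, df$lrr_sd, df$baf_drift, df$wave_factor)
}

#' @rdname read_sample_qc
#' @param qc A `sample_qc` tibble.
#' @export
write_sample_qc <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export CNVRs as BED6 plus a full-field TSV sidecar
#'
#' Internal coordinates are 1-based closed; BED is 0-based half-open, so the
#' BED start is `start - 1` and the BED end equals the internal end. The
#' sidecar (`<path>.tsv`) carries every region column and allows exact
#' reconstruction with [read_cnvr_bed()].
#'
#' @param regions A CNVR tibble from [call_cnvr()], sorted by (chrom, start).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# CNVR export: chrom, start (0-based), end, region_id, n_samples, type", con)
  if (nrow(regions)) {
    ord <- order(regions$chrom, regions$start)
    if (!identical(ord, seq_len(nrow(regions))))
      regions <- regions[ord, ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       regions$chrom, regions$start - 1L, regions$end,
                       regions$region_id, regions$n_samples, regions$type), con)
  }
  utils::write.table(regions, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvr_bed
#' @export
read_cnvr_bed <- function(path) {
  df <- utils::read.delim(paste0(path, ".tsv"), colClasses = list(chrom = "character"))
  tibble::as_tibble(df)
}
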