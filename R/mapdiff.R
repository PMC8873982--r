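# Cross-assembly SNP-manifest comparison: category partition of the marker
# union, per-chromosome density, and position/order concordance.

.map_categories <- c("same_chromosome", "both_unknown", "different_chromosomes",
                     "unknown_in_A", "unknown_in_B",
                     "missing_from_A", "missing_from_B")

#' Classify marker pairs between two manifests
#'
#' Every marker name in the union of the two maps falls in exactly one of
#' seven categories: placed on the same chromosome in both, unplaced in
#' both, placed on different chromosomes, unplaced in only one map, or
#' absent from one map entirely. "Same chromosome" does not require equal
#' positions — position and order disagreement is the business of
#' [position_concordance()].
#'
#' @param map_a,map_b `snp_map` tibbles of the same array under two builds.
#' @return A list with `counts` (tibble: category, n, pct_in_A, pct_in_B,
#'   percentages of each map's marker total) and `per_marker` (tibble:
#'   name, category).
#' @export
classify_marker_pairs <- function(map_a, map_b) {
  all_names <- union(map_a$name, map_b$name)
  ia <- match(all_names, map_a$name)
  ib <- match(all_names, map_b$name)
  chrom_a <- map_a$chrom[ia]
  chrom_b <- map_b$chrom[ib]
  category <- dplyr::case_when(
    is.na(ia) ~ "missing_from_A",
    is.na(ib) ~ "missing_from_B",
    is.na(chrom_a) & is.na(chrom_b) ~ "both_unknown",
    is.na(chrom_a) ~ "unknown_in_A",
    is.na(chrom_b) ~ "unknown_in_B",
    chrom_a == chrom_b ~ "same_chromosome",
    TRUE ~ "different_chromosomes"
  )
  n <- vapply(.map_categories, function(k) sum(category == k), 0L)
  counts <- tibble::tibble(
    category = .map_categories,
    n = as.integer(n),
    pct_in_A = ifelse(.map_categories == "missing_from_A", NA_real_,
                      proportion_pct(n, nrow(map_a))),
    pct_in_B = ifelse(.map_categories == "missing_from_B", NA_real_,
                      proportion_pct(n, nrow(map_b)))
  )
  list(counts = counts,
       per_marker = tibble::tibble(name = all_names, category = category))
}

#' Per-chromosome SNP density
#'
#' Density in markers per Mb of chromosome length. Lengths come from the
#' genome build when supplied; otherwise the last mapped position on each
#' chromosome stands in for its length (flagged in the output).
#'
#' @param map An `snp_map` tibble.
#' @param genome Optional [genome_build()].
#' @return A tibble: `chrom`, `n_snps`, `length_bp`, `snps_per_mb`,
#'   `length_source`.
#' @export
snp_density <- function(map, genome = NULL) {
  placed <- map[!is.na(map$chrom), ]
  counts <- dplyr::summarise(dplyr::group_by(placed, .data$chrom),
                             n_snps = dplyr::n(),
                             max_pos = max(.data$pos), .groups = "drop")
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_build"))
    chroms <- names(genome$chrom_lengths)
    out <- tibble::tibble(chrom = chroms,
                          n_snps = counts$n_snps[match(chroms, counts$chrom)],
                          length_bp = unname(genome$chrom_lengths),
                          length_source = "genome")
    out$n_snps[is.na(out$n_snps)] <- 0L
    if (any(out$n_snps == 0L))
      warning("chromosome(s) with no mapped markers: ",
              paste(out$chrom[out$n_snps == 0L], collapse = ", "))
  } else {
    out <- tibble::tibble(chrom = counts$chrom, n_snps = counts$n_snps,
                          length_bp = as.numeric(counts$max_pos),
                          length_source = "max_position")
  }
  out$snps_per_mb <- out$n_snps / (out$length_bp / 1e6)
  out
}

# number of discordant pairs = inversions of `y` taken in x-order
# (mergesort, O(n log n))
count_inversions <- function(y) {
  rec <- function(v) {
    n <- length(v)
    if (n <= 1L) return(list(v = v, inv = 0))
    mid <- n %/% 2L
    L <- rec(v[seq_len(mid)]); R <- rec(v[(mid + 1L):n])
    merged <- numeric(n); inv <- L$inv + R$inv
    i <- 1L; j <- 1L
    for (k in seq_len(n)) {
      if (i <= length(L$v) && (j > length(R$v) || L$v[i] <= R$v[j])) {
        merged[k] <- L$v[i]; i <- i + 1L
      } else {
        merged[k] <- R$v[j]; j <- j + 1L
        inv <- inv + (length(L$v) - i + 1L)
      }
    }
    list(v = merged, inv = inv)
  }
  rec(y)$inv
}

#' Position and order concordance between two manifests
#'
#' Restricted to markers placed in both maps. For each chromosome shared by
#' a marker pair, emits the paired positions and ranks (the dot-plot data)
#' and counts the discordant pairs: pairs of markers whose relative order
#' flips between the maps (a Kendall-type count; 0 for identical order).
#' Markers placed on different chromosomes are returned separately.
#'
#' @param map_a,map_b `snp_map` tibbles.
#' @return A list with `pairs` (name, chrom, pos_a, pos_b, rank_a, rank_b),
#'   `discordance` (chrom, n_markers, n_discordant_pairs, frac_discordant)
#'   and `cross_chromosome` (markers mapped to different chromosomes).
#' @export
position_concordance <- function(map_a, map_b) {
  shared <- intersect(map_a$name[!is.na(map_a$chrom)],
                      map_b$name[!is.na(map_b$chrom)])
  ia <- match(shared, map_a$name); ib <- match(shared, map_b$name)
  same <- map_a$chrom[ia] == map_b$chrom[ib]
  cross <- tibble::tibble(name = shared[!same],
                          chrom_a = map_a$chrom[ia][!same],
                          pos_a = map_a$pos[ia][!same],
                          chrom_b = map_b$chrom[ib][!same],
                          pos_b = map_b$pos[ib][!same])
  df <- tibble::tibble(name = shared[same],
                       chrom = map_a$chrom[ia][same],
                       pos_a = map_a$pos[ia][same],
                       pos_b = map_b$pos[ib][same])
  pairs <- dplyr::bind_rows(lapply(split(df, df$chrom), function(g) {
    g <- g[order(g$pos_a), ]
    g$rank_a <- seq_len(nrow(g))
    g$rank_b <- rank(g$pos_b, ties.method = "first")
    g
  }))
  discordance <- dplyr::bind_rows(lapply(split(pairs, pairs$chrom), function(g) {
    n <- nrow(g)
    inv <- count_inversions(g$rank_b[order(g$rank_a)])
    tibble::tibble(chrom = g$chrom[1], n_markers = n,
                   n_discordant_pairs = inv,
                   frac_discordant = if (n > 1) inv / choose(n, 2) else 0)
  }))
  list(pairs = pairs, discordance = discordance, cross_chromosome = cross)
}
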