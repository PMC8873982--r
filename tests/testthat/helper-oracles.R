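# Independent brute-force oracles. Deliberately naive: union-find over an
# all-pairs overlap scan, per-basepair coverage masks, and O(n^2) pair
# scans, none of which share code with the implementation under test.

# connected components of the >=1-bp overlap graph, via union-find
oracle_cnvr <- function(calls) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (calls$chrom[i] == calls$chrom[j] &&
        calls$start[i] <= calls$end[j] && calls$start[j] <= calls$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    m <- comp == k
    data.frame(chrom = calls$chrom[m][1],
               start = min(calls$start[m]), end = max(calls$end[m]),
               type = classify_cnv_type(calls$cn[m]),
               n_calls = sum(m),
               n_samples = length(unique(calls$sample_id[m])))
  }))
  out[order(suppressWarnings(as.numeric(out$chrom)), out$chrom, out$start), ,
      drop = FALSE]
}

# bp covered by both interval sets, by marking coverage masks
oracle_overlap_length <- function(a, b, chrom_len) {
  total <- 0
  for (chr in union(a$chrom, b$chrom)) {
    ma <- logical(chrom_len); mb <- logical(chrom_len)
    for (i in which(a$chrom == chr)) ma[a$start[i]:a$end[i]] <- TRUE
    for (i in which(b$chrom == chr)) mb[b$start[i]:b$end[i]] <- TRUE
    total <- total + sum(ma & mb)
  }
  total
}

# per-direction overlapped-call counts via an all-pairs scan
oracle_compare_cnv <- function(a, b, level) {
  hit_count <- function(x, y) {
    hits <- 0L
    for (i in seq_len(nrow(x))) {
      found <- FALSE
      for (j in seq_len(nrow(y))) {
        ok <- x$chrom[i] == y$chrom[j] &&
          x$start[i] <= y$end[j] && y$start[j] <= x$end[i]
        if (ok && level == "individual")
          ok <- x$sample_id[i] == y$sample_id[j]
        if (ok) { found <- TRUE; break }
      }
      if (found) hits <- hits + 1L
    }
    hits
  }
  c(a_hits = hit_count(a, b), b_hits = hit_count(b, a))
}

# fixed point of repeated first-found pairwise gap-merging (span denominator)
oracle_merge_group <- function(df, fraction) {
  repeat {
    df <- df[order(df$start), , drop = FALSE]
    n <- nrow(df)
    merged <- FALSE
    for (i in seq_len(max(n - 1L, 0L))) {
      gap <- df$start[i + 1L] - df$end[i] - 1L
      span <- max(df$end[i], df$end[i + 1L]) - df$start[i] + 1L
      if (gap < 0L || gap / span < fraction) {
        df$end[i] <- max(df$end[i], df$end[i + 1L])
        df$n_snp[i] <- df$n_snp[i] + df$n_snp[i + 1L]
        df <- df[-(i + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(df)
  }
}

# discordant order pairs by exhaustive scan
oracle_discordant_pairs <- function(pos_a, pos_b) {
  n <- length(pos_a)
  count <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sign(pos_a[i] - pos_a[j]) != sign(pos_b[i] - pos_b[j]))
      count <- count + 1L
  }
  count
}

# random call table on a small genome
random_calls <- function(n, n_chrom = 3, chrom_len = 1e4, n_samples = 5,
                         max_len = 2000) {
  start <- sample.int(chrom_len - 10L, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  cnv_calls(sample(sprintf("S%d", seq_len(n_samples)), n, replace = TRUE),
            sample(as.character(seq_len(n_chrom)), n, replace = TRUE),
            start, pmin(start + len, chrom_len),
            sample(c(0L, 1L, 3L, 4L), n, replace = TRUE))
}

# random region table (distinct ids) for region-level comparisons
random_regions <- function(n, n_chrom = 3, chrom_len = 1e4, prefix = "R") {
  calls <- random_calls(n, n_chrom, chrom_len)
  tibble::tibble(region_id = sprintf("%s_%d", prefix, seq_len(n)),
                 chrom = calls$chrom, start = calls$start, end = calls$end,
                 type = sample(c("gain", "loss", "mixed"), n, replace = TRUE),
                 n_samples = sample(30L, n, replace = TRUE))
}
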