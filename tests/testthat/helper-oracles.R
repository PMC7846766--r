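# Independent brute-force oracles. These deliberately avoid the package's
# GenomicRanges-based code paths: everything is plain vectors and quadratic
# scans, so they can arbitrate the fast implementations.

# random interval set on one chromosome, BED 0-based half-open
random_intervals <- function(n, chrom = "chr1", L = 1e6, max_len = 5000) {
  start0 <- floor(runif(n) * (L - max_len))
  len <- pmax(1, floor(runif(n) * max_len))
  data.frame(chrom = chrom, start = start0, end = start0 + len,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# quadratic overlap mask: does query i overlap any subject? (half-open)
oracle_overlap_mask <- function(qdf, sdf) {
  vapply(seq_len(nrow(qdf)), function(i) {
    any(sdf$chrom == qdf$chrom[i] &
          pmax(sdf$start, qdf$start[i]) < pmin(sdf$end, qdf$end[i]))
  }, logical(1))
}

# per-bp accumulation of track mass over a region (0-based coordinates)
oracle_region_signal <- function(track_df, region) {
  bp <- seq(region$start, region$end - 1)
  val <- numeric(length(bp))
  for (i in seq_len(nrow(track_df))) {
    if (track_df$chrom[i] != region$chrom) next
    inside <- bp >= track_df$start[i] & bp < track_df$end[i]
    val[inside] <- val[inside] + track_df$value[i]
  }
  sum(val)
}

# exhaustive slope-1 elbow: scaled difference argmin, largest-index ties
oracle_elbow <- function(scores) {
  y <- sort(scores)
  n <- length(y)
  x <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - min(y)) / (max(y) - min(y))
  d <- ys - x
  idx <- max(which(d == min(d)))
  list(cutoff_index = idx, cutoff_value = y[idx])
}

# transitive merge of intervals with gap < window (plus abut/overlap)
oracle_stitch <- function(df, window) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    gap <- df$start[i] - cur$end
    if (df$chrom[i] == cur$chrom && (gap < window || gap <= 0)) {
      cur$end <- max(cur$end, df$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- df[i, , drop = FALSE]
    }
  }
  out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

# state-pair enrichment by direct enumeration of anchor slots
oracle_pair_enrichment <- function(s1, s2) {
  n <- length(s1)
  states <- sort(unique(c(s1, s2)))
  slots <- c(s1, s2)
  p <- vapply(states, function(s) sum(slots == s) / (2 * n), numeric(1))
  rows <- list()
  for (a in states) for (b in states) {
    if (a > b) next
    obs <- sum((s1 == a & s2 == b) | (s1 == b & s2 == a)) / n
    if (a == b) obs <- sum(s1 == a & s2 == a) / n
    e <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
    rows[[length(rows) + 1]] <- data.frame(
      pair = paste0(a, b), observed_prop = obs, expected_prop = e,
      log2_ratio = if (obs > 0) log2(obs / e) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
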