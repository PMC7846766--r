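# Calling H3K27me3-rich regions (MRRs, candidate super-silencers) and
# super-enhancers: stitch nearby peaks, score stitched regions against a
# control track, rank, and cut the ranked curve where its slope reaches 1.

#' Stitch nearby peaks into regions
#'
#' Consecutive peaks on the same chromosome are merged iff the gap between
#' them (next start minus current end, BED convention) is strictly less than
#' `window`; abutting or overlapping peaks are always merged. Every input
#' peak is recorded as a constituent of exactly one stitched region.
#'
#' @param peaks `GRanges` of peaks (non-empty).
#' @param window stitching window in bp (>= 0); 4000 for H3K27me3 MRR
#'   calling, 12500 for H3K27ac super-enhancers.
#' @return A `GRanges` of stitched regions with metadata columns
#'   `n_constituents` and `constituents` (an integer list mapping back to
#'   rows of the sorted input, returned as attribute `peak_order`).
#' @export
stitch_peaks <- function(peaks, window) {
  if (length(peaks) == 0) stop("empty peak list")
  if (window < 0) stop("window must be >= 0")
  peaks <- GenomicRanges::sort(GenomicRanges::granges(peaks),
                               ignore.strand = TRUE)
  # reduce() merges ranges whose 1-based gap < min.gapwidth; the 1-based gap
  # equals the BED gap (next.start - current.end), so min.gapwidth = window
  # implements "gap < window"; min 1 keeps abutting/overlapping always merged
  merged <- GenomicRanges::reduce(peaks,
                                  min.gapwidth = max(window, 1),
                                  ignore.strand = TRUE,
                                  with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  out <- GenomicRanges::granges(merged)
  S4Vectors::mcols(out)$n_constituents <- lengths(revmap)
  S4Vectors::mcols(out)$constituents <- revmap
  attr(out, "peak_order") <- peaks
  attr(out, "window") <- window
  out
}

#' Score stitched regions against treatment and control signal
#'
#' Default scoring follows the total-signal convention of super-enhancer
#' callers: treatment minus control value-bp over the stitched interval,
#' floored at 0. `mode = "density"` divides by interval length to rank by
#' average signal instead; which was used is recorded on the result.
#'
#' @param regions stitched regions from [stitch_peaks()].
#' @param treatment signal track `GRanges`.
#' @param control optional signal track; absent means control signal 0.
#' @param mode "total" (default) or "density".
#' @return `regions` with metadata columns `treatment_signal`,
#'   `control_signal`, `score`.
#' @export
score_regions <- function(regions, treatment, control = NULL,
                          mode = c("total", "density")) {
  mode <- match.arg(mode)
  trt <- region_signal(treatment, regions)
  ctl <- if (is.null(control)) numeric(length(regions))
         else region_signal(control, regions)
  score <- pmax(0, trt - ctl)
  if (mode == "density") score <- score / GenomicRanges::width(regions)
  S4Vectors::mcols(regions)$treatment_signal <- trt
  S4Vectors::mcols(regions)$control_signal <- ctl
  S4Vectors::mcols(regions)$score <- score
  attr(regions, "score_mode") <- mode
  regions
}

#' Slope-1 cutoff on a ranked score curve
#'
#' Scores are sorted ascending and both axes scaled to \[0, 1\]; the cutoff
#' is the point minimizing scaled-score minus scaled-rank (the point where a
#' unit-slope tangent touches the hockey-stick curve), ties broken toward
#' the largest index. Scores strictly above the cutoff value are "rich".
#'
#' @param scores numeric vector of region scores.
#' @return A list of class `ranked_cutoff` with elements `y` (sorted
#'   scores), `x` and `y_scaled` (the scaled curve), `cutoff_index` (into
#'   the sorted order), `cutoff_value`, `degenerate` (logical) and `rich`
#'   (logical along the *input* order).
#' @export
slope_cutoff <- function(scores) {
  n <- length(scores)
  if (n == 0) stop("no scores")
  o <- order(scores)
  y <- scores[o]
  degenerate <- n < 3 || max(y) == min(y)
  if (degenerate) {
    warning("degenerate ranked curve (n < 3 or constant scores): ",
            "no rich regions called")
    res <- list(y = y, x = rep(NA_real_, n), y_scaled = rep(NA_real_, n),
                cutoff_index = NA_integer_, cutoff_value = Inf,
                degenerate = TRUE, rich = rep(FALSE, n))
    class(res) <- "ranked_cutoff"
    return(res)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - min(y)) / (max(y) - min(y))
  d <- ys - x
  cutoff_index <- max(which(d == min(d)))
  cutoff_value <- y[cutoff_index]
  res <- list(y = y, x = x, y_scaled = ys, cutoff_index = cutoff_index,
              cutoff_value = cutoff_value, degenerate = FALSE,
              rich = scores > cutoff_value)
  class(res) <- "ranked_cutoff"
  res
}

#' Call rich regions (MRRs or super-enhancers) from peaks and signal
#'
#' Orchestrates stitch -> score -> rank -> slope-1 cutoff. The default
#' stitching window is resolved from the mark: 4 kb for H3K27me3 (MRR
#' calling), 12.5 kb for H3K27ac (super-enhancer calling).
#'
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param treatment,control signal tracks (control optional).
#' @param mark "H3K27me3" or "H3K27ac".
#' @param window stitching window in bp; default resolved from `mark`.
#' @param score_mode "total" or "density" (see [score_regions()]).
#' @return Scored stitched regions (`GRanges`) with `score`, `rank`
#'   (1 = highest score) and `label` ("rich" or "typical") metadata; the
#'   ranked curve is attached as attribute `curve`.
#' @export
call_regions <- function(peaks, treatment, control = NULL,
                         mark = c("H3K27me3", "H3K27ac"),
                         window = NULL,
                         score_mode = c("total", "density")) {
  mark <- match.arg(mark)
  if (is.null(window))
    window <- switch(mark, H3K27me3 = 4000, H3K27ac = 12500)
  regions <- stitch_peaks(peaks, window)
  regions <- score_regions(regions, treatment, control,
                           mode = match.arg(score_mode))
  sc <- S4Vectors::mcols(regions)$score
  curve <- slope_cutoff(sc)
  S4Vectors::mcols(regions)$rank <- rank(-sc, ties.method = "first")
  S4Vectors::mcols(regions)$label <- ifelse(curve$rich, "rich", "typical")
  attr(regions, "curve") <- curve
  attr(regions, "mark") <- mark
  attr(regions, "window") <- window
  regions
}

#' Presence of rich regions across samples
#'
#' A rich region from one sample is "present" in another sample iff some
#' rich region there overlaps it by at least `min_overlap_fraction` of the
#' shorter of the two regions.
#'
#' @param region_sets named list (>= 2 samples) of called region `GRanges`
#'   (with `label` metadata; only "rich" regions are considered).
#' @param min_overlap_fraction required overlap as a fraction of the shorter
#'   region, in (0, 1].
#' @return Logical matrix: one row per rich source region (rownames
#'   `sample:chrom:start-end`), one column per sample.
#' @export
presence_across_samples <- function(region_sets, min_overlap_fraction = 0.5) {
  if (length(region_sets) < 2) stop("need >= 2 samples")
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  rich_sets <- lapply(region_sets, function(gr) {
    lab <- S4Vectors::mcols(gr)$label
    if (is.null(lab)) gr else gr[lab == "rich"]
  })
  rows <- list(); rn <- character()
  for (s in names(rich_sets)) {
    src <- rich_sets[[s]]
    if (length(src) == 0) next
    mat <- sapply(names(rich_sets), function(t) {
      .fraction_overlap_any(src, rich_sets[[t]], min_overlap_fraction)
    })
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1,
                                         dimnames = list(NULL, names(rich_sets)))
    rows[[s]] <- mat
    rn <- c(rn, paste0(s, ":", as.character(GenomicRanges::seqnames(src)), ":",
                       GenomicRanges::start(src) - 1, "-",
                       GenomicRanges::end(src)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- rn
  out
}

# does any subject region overlap each query by >= frac of the shorter one?
.fraction_overlap_any <- function(query, subject, frac) {
  out <- rep(FALSE, length(query))
  if (length(subject) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(query, subject)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(query)[q], GenomicRanges::end(subject)[s]) -
    pmax(GenomicRanges::start(query)[q], GenomicRanges::start(subject)[s]) + 1
  shorter <- pmin(GenomicRanges::width(query)[q],
                  GenomicRanges::width(subject)[s])
  ok <- ov >= frac * shorter
  out[unique(q[ok])] <- TRUE
  out
}
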