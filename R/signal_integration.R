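# ChIP-seq signal areas over regions, tertile state labeling, TF-peak
# Z-score matrices, and the joint 4C-status x histone-state tables.

#' Binned signal and total signal area over a region
#'
#' The region is tiled left to right in bins of `bin_size` bp (the final
#' bin truncated to the region end); the per-bin value is the mean track
#' value over the bin (absent coverage = 0, deeptools computeMatrix
#' semantics), and Total Signal Area = sum(Sig * BS) with the truncated
#' final bin contributing its true width.
#'
#' @param track signal track `GRanges`.
#' @param region single-interval `GRanges`.
#' @param bin_size bin width in bp (>= 1).
#' @return list: `bins` (`GRanges`), `values` (mean signal per bin),
#'   `total_area` (value-bp).
#' @export
signal_area <- function(track, region, bin_size = 50) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  stopifnot(length(region) == 1)
  s <- GenomicRanges::start(region); e <- GenomicRanges::end(region)
  starts <- seq(s, e, by = bin_size)
  ends <- pmin(starts + bin_size - 1, e)
  bins <- GenomicRanges::GRanges(GenomicRanges::seqnames(region),
                                 IRanges::IRanges(starts, ends))
  mass <- region_signal(track, bins)
  widths <- GenomicRanges::width(bins)
  values <- mass / widths
  list(bins = bins, values = values, total_area = sum(values * widths))
}

#' Tertile labels (high / medium / low)
#'
#' Boundaries at the 1/3 and 2/3 quantiles (linear interpolation); a value
#' <= the lower boundary is "low" (checked first), >= the upper is "high",
#' else "medium". Degenerate all-equal cohorts are therefore all "low" (a
#' warning is emitted).
#'
#' @param values numeric vector, n >= 3.
#' @return character vector along `values`.
#' @export
tertile_labels <- function(values) {
  if (length(values) < 3) stop("need >= 3 values for tertiles")
  q <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (q[1] == q[2] && stats::sd(values) == 0)
    warning("all values equal; tertile labels degenerate to 'low'")
  ifelse(values <= q[1], "low", ifelse(values >= q[2], "high", "medium"))
}

#' TF-binding Z-score matrix over interacting regions
#'
#' Counts, per region, the overlapping peaks of each transcription factor,
#' then standardizes each TF column to a Z score across regions; a TF with
#' zero count variance gets Z = 0 everywhere.
#'
#' @param regions `GRanges` (>= 2 regions), e.g. interacting regions of
#'   MRRs.
#' @param tf_peaksets named list of `GRanges` peak sets.
#' @return numeric matrix regions x TFs; raw counts attached as attribute
#'   `counts`.
#' @export
tf_zscore_matrix <- function(regions, tf_peaksets) {
  if (length(regions) < 2) stop("need >= 2 regions")
  counts <- sapply(tf_peaksets, function(pk)
    GenomicRanges::countOverlaps(regions, pk))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(regions),
                     dimnames = list(NULL, names(tf_peaksets)))
  z <- apply(counts, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  if (is.null(dim(z)))
    z <- matrix(z, nrow = length(regions),
                dimnames = list(NULL, names(tf_peaksets)))
  attr(z, "counts") <- counts
  z
}

#' Integrate 4C comparison status with ChIP-seq signal areas
#'
#' For every 4C region of a comparison, computes H3K27me3 and H3K27ac total
#' signal areas per condition, labels the control-condition signal tertile
#' per mark, reports log10 RPM per condition, and runs a paired Wilcoxon
#' test of control vs experiment area per status group and mark.
#'
#' @param comparison output of [bait_distance()] (or
#'   [compare_conditions()]).
#' @param k27me3_control,k27me3_experiment,k27ac_control,k27ac_experiment
#'   signal tracks; all four are required.
#' @param bin_size bin width for [signal_area()] (default 50 bp).
#' @return list: `records` data.frame (per 4C region: status, areas per mark
#'   and condition, tertiles in control, log10 RPMs, area deltas) and
#'   `paired_tests` data.frame (status x mark with paired Wilcoxon p).
#' @export
integrate_fourc_chip <- function(comparison,
                                 k27me3_control, k27me3_experiment,
                                 k27ac_control, k27ac_experiment,
                                 bin_size = 50) {
  for (tr in list(k27me3_control, k27me3_experiment,
                  k27ac_control, k27ac_experiment))
    if (is.null(tr)) stop("all four condition tracks are required")
  regions <- GenomicRanges::GRanges(comparison$chrom,
                                    IRanges::IRanges(comparison$start + 1,
                                                     comparison$end))
  area_over <- function(track) vapply(seq_along(regions), function(i)
    signal_area(track, regions[i], bin_size)$total_area, numeric(1))
  rec <- comparison
  rec$k27me3_area_control <- area_over(k27me3_control)
  rec$k27me3_area_experiment <- area_over(k27me3_experiment)
  rec$k27ac_area_control <- area_over(k27ac_control)
  rec$k27ac_area_experiment <- area_over(k27ac_experiment)
  rec$k27me3_delta <- rec$k27me3_area_experiment - rec$k27me3_area_control
  rec$k27ac_delta <- rec$k27ac_area_experiment - rec$k27ac_area_control
  rec$k27me3_tertile <- if (nrow(rec) >= 3)
    tertile_labels(rec$k27me3_area_control) else rep(NA_character_, nrow(rec))
  rec$k27ac_tertile <- if (nrow(rec) >= 3)
    tertile_labels(rec$k27ac_area_control) else rep(NA_character_, nrow(rec))
  if (!is.null(rec$control_rpm))
    rec$control_rpm_log10 <- log10(rec$control_rpm)
  if (!is.null(rec$experiment_rpm))
    rec$experiment_rpm_log10 <- log10(rec$experiment_rpm)
  tests <- do.call(rbind, lapply(unique(rec$status), function(st) {
    sub <- rec[rec$status == st, , drop = FALSE]
    one <- function(a, b) {
      if (nrow(sub) < 2 || all(a == b)) return(NA_real_)
      # normal approximation: ties are routine in signal areas
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    }
    data.frame(status = st,
               k27me3_paired_p = one(sub$k27me3_area_control,
                                     sub$k27me3_area_experiment),
               k27ac_paired_p = one(sub$k27ac_area_control,
                                    sub$k27ac_area_experiment),
               stringsAsFactors = FALSE)
  }))
  list(records = rec, paired_tests = tests)
}
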