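# Peak stitching, region scoring, the slope-1 rank cutoff, and cross-sample
# presence of called regions.

test_that("stitching merges peaks by the gap < window rule", {
  peaks <- df_to_gr(data.frame(chrom = "chr1",
                               start = c(0, 3000, 8000),
                               end = c(100, 3100, 8100)))
  st <- stitch_peaks(peaks, 4000)  # gaps 2900 (<4000) and 4900 (>=4000)
  expect_equal(gr_to_df(st)[, c("start", "end")],
               data.frame(start = c(0, 8000), end = c(3100, 8100)))
  expect_equal(S4Vectors::mcols(st)$n_constituents, c(2, 1))

  # single peak is returned unchanged
  one <- stitch_peaks(peaks[1], 4000)
  expect_equal(gr_to_df(one)[, c("start", "end")],
               data.frame(start = 0, end = 100))

  # window 0: only overlapping/abutting peaks merge
  st0 <- stitch_peaks(peaks, 0)
  expect_equal(length(st0), 3)
  expect_error(stitch_peaks(GenomicRanges::GRanges(), 4000), "empty")
})

test_that("fuzzed stitching matches the transitive-merge oracle", {
  set.seed(52)
  for (rep in 1:30) {
    df <- random_intervals(sample(2:40, 1), L = 3e5, max_len = 3000)
    w <- sample(c(0, 500, 4000, 12500), 1)
    got <- gr_to_df(stitch_peaks(df_to_gr(df), w))
    want <- oracle_stitch(df, w)
    rownames(want) <- NULL
    expect_equal(got, want[, c("chrom", "start", "end")])
  }
})

test_that("scoring subtracts control with a floor at zero", {
  region <- stitch_peaks(df_to_gr(data.frame(chrom = "chr1", start = 0,
                                             end = 1000)), 4000)
  trt <- signal_track("chr1", 0, 1000, 3.0)
  ctl <- signal_track("chr1", 0, 1000, 1.0)
  sc <- score_regions(region, trt, ctl)
  expect_equal(S4Vectors::mcols(sc)$score, 2000)  # (3 - 1) x 1000

  # control exceeding treatment floors at 0
  sc0 <- score_regions(region, ctl, trt)
  expect_equal(S4Vectors::mcols(sc0)$score, 0)

  # density mode divides by interval length
  scd <- score_regions(region, trt, ctl, mode = "density")
  expect_equal(S4Vectors::mcols(scd)$score, 2)

  # absent control means control signal 0
  scn <- score_regions(region, trt)
  expect_equal(S4Vectors::mcols(scn)$control_signal, 0)
})

test_that("slope-1 cutoff follows the scaled-curve argmin with tie-break", {
  cur <- slope_cutoff(c(1, 1, 1, 10))
  expect_equal(cur$cutoff_index, 3)        # differences 0, -1/3, -2/3, 0
  expect_equal(cur$cutoff_value, 1)
  expect_equal(sum(cur$rich), 1)           # only the 10

  # perfectly linear curve: all differences 0, tie -> largest index
  lin <- slope_cutoff(c(2, 4, 6, 8, 10))
  expect_equal(lin$cutoff_index, 5)
  expect_false(any(lin$rich))

  expect_warning(deg <- slope_cutoff(c(5, 5, 5, 5)), "degenerate")
  expect_false(any(deg$rich))
})

test_that("cutoff index is invariant to shift and positive scaling", {
  set.seed(61)
  for (rep in 1:20) {
    y <- rlnorm(sample(5:200, 1), 3, 1)
    base <- slope_cutoff(y)$cutoff_index
    expect_equal(slope_cutoff(y + 17.3)$cutoff_index, base)
    expect_equal(slope_cutoff(y * 4.2)$cutoff_index, base)
  }
})

test_that("mark-specific default stitching windows are applied", {
  peaks <- df_to_gr(data.frame(chrom = "chr1",
                               start = c(0, 5000, 20000),
                               end = c(1000, 6000, 21000)))
  trt <- signal_track("chr1", 0, 30000, 2.0)
  # H3K27me3: window 4000 -> gap 4000 not merged, three regions
  # (constant-signal scores make the ranked curve degenerate, by design)
  me3 <- suppressWarnings(call_regions(peaks, trt, mark = "H3K27me3"))
  expect_equal(attr(me3, "window"), 4000)
  expect_equal(length(me3), 3)
  # H3K27ac: window 12500 -> first two merge
  ac <- suppressWarnings(call_regions(peaks, trt, mark = "H3K27ac"))
  expect_equal(attr(ac, "window"), 12500)
  expect_equal(length(ac), 2)
})

test_that("stitched region count is non-increasing in window size", {
  set.seed(71)
  df <- random_intervals(60, L = 5e5, max_len = 2000)
  counts <- vapply(c(0, 1000, 4000, 12500, 50000), function(w)
    length(stitch_peaks(df_to_gr(df), w)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("presence across samples matches a quadratic overlap-fraction oracle", {
  set.seed(81)
  mk <- function(df) {
    gr <- df_to_gr(df)
    S4Vectors::mcols(gr)$label <- "rich"
    gr
  }
  a <- random_intervals(15, L = 2e5, max_len = 4000)
  sets <- list(s1 = mk(a),
               s2 = mk(data.frame(chrom = "chr1", start = a$start + 1500,
                                  end = a$end + 1500)),
               s3 = mk(random_intervals(10, L = 2e5, max_len = 4000)))
  frac <- 0.5
  mat <- presence_across_samples(sets, frac)
  # oracle: region present in sample t iff some region there overlaps it
  # by >= frac of the shorter region
  oracle_present <- function(q, set) {
    any(vapply(seq_len(nrow(set)), function(j) {
      if (set$chrom[j] != q$chrom) return(FALSE)
      ov <- min(set$end[j], q$end) - max(set$start[j], q$start)
      ov >= frac * min(set$end[j] - set$start[j], q$end - q$start)
    }, logical(1)))
  }
  k <- 0
  for (s in names(sets)) {
    src <- gr_to_df(sets[[s]])
    for (i in seq_len(nrow(src))) {
      k <- k + 1
      for (t in names(sets))
        expect_equal(unname(mat[k, t]),
                     oracle_present(src[i, ], gr_to_df(sets[[t]])))
    }
  }
  # identical sets are present everywhere
  mat2 <- presence_across_samples(list(x = sets$s1, y = sets$s1), 0.5)
  expect_true(all(mat2))
  expect_error(presence_across_samples(sets, 0), "fraction")
})

test_that("stitching never loses or duplicates constituent peaks", {
  set.seed(91)
  for (rep in 1:10) {
    df <- random_intervals(sample(5:50, 1), L = 4e5, max_len = 2500)
    st <- stitch_peaks(df_to_gr(df), 4000)
    idx <- sort(unlist(S4Vectors::mcols(st)$constituents))
    expect_equal(idx, seq_len(nrow(df)))
  }
})
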