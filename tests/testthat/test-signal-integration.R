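# Binned signal areas, tertile labels, TF Z-score matrices and the joint
# 4C-status x ChIP-signal records.

test_that("signal area follows sum(Sig * BS) with a truncated final bin", {
  # two 50 bp bins with mean signal 2 and 4 -> 2x50 + 4x50 = 300
  tr <- signal_track(c("chr1", "chr1"), c(0, 50), c(50, 100), c(2, 4))
  region <- df_to_gr(data.frame(chrom = "chr1", start = 0, end = 100))
  sa <- signal_area(tr, region, bin_size = 50)
  expect_equal(sa$values, c(2, 4))
  expect_equal(sa$total_area, 300)
  # zero track
  expect_equal(signal_area(signal_track(character(), numeric(), numeric(),
                                        numeric()),
                           region, 50)$total_area, 0)
  # truncated final bin uses its true width
  region2 <- df_to_gr(data.frame(chrom = "chr1", start = 0, end = 80))
  sa2 <- signal_area(tr, region2, bin_size = 50)
  expect_equal(GenomicRanges::width(sa2$bins), c(50, 30))
  expect_equal(sa2$total_area, 2 * 50 + 4 * 30)
  expect_error(signal_area(tr, region, 0), "bin_size")
})

test_that("signal area at 1 bp bins equals region_signal exactly", {
  set.seed(501)
  starts <- sort(sample(seq(0, 4800, by = 120), 25))
  tr <- signal_track(rep("chr1", 25), starts, starts + 100,
                     round(runif(25, 0, 4), 2))
  for (rep in 1:5) {
    s0 <- sample(0:4000, 1)
    region <- df_to_gr(data.frame(chrom = "chr1", start = s0,
                                  end = s0 + sample(200:900, 1)))
    expect_equal(signal_area(tr, region, bin_size = 1)$total_area,
                 region_signal(tr, region))
  }
  # bin_size = region length reduces to mean x length = region_signal
  region <- df_to_gr(data.frame(chrom = "chr1", start = 100, end = 1400))
  expect_equal(signal_area(tr, region, bin_size = 1300)$total_area,
               region_signal(tr, region))
})

test_that("tertile labels follow the quantile boundaries and tie rules", {
  expect_equal(tertile_labels(1:9),
               rep(c("low", "medium", "high"), each = 3))
  expect_warning(lab <- tertile_labels(rep(2, 5)), "degenerate")
  expect_true(all(lab == "low"))
  expect_error(tertile_labels(c(1, 2)), "3")
  # label multiset invariant under strictly monotone transforms
  set.seed(511)
  v <- rlnorm(30)
  expect_equal(tertile_labels(v), tertile_labels(log(v)))
  expect_equal(tertile_labels(v), tertile_labels(v^3))
})

test_that("TF Z-score matrix standardizes per factor with the sd-zero rule", {
  regions <- df_to_gr(data.frame(chrom = "chr1",
                                 start = c(0, 1e4, 2e4),
                                 end = c(5e3, 1.5e4, 2.5e4)))
  tf <- list(
    ctcf = df_to_gr(data.frame(chrom = "chr1",
                               start = c(2e4, 21e3, 22e3),
                               end = c(20500, 21500, 22500))),
    rest = df_to_gr(data.frame(chrom = "chr1", start = c(100, 10100, 20100),
                               end = c(200, 10200, 20200))))
  z <- tf_zscore_matrix(regions, tf)
  counts <- attr(z, "counts")
  expect_equal(unname(counts[, "ctcf"]), c(0, 0, 3))
  # direct standardization oracle
  expect_equal(unname(z[, "ctcf"]), (c(0, 0, 3) - 1) / sd(c(0, 0, 3)))
  # constant counts give z = 0
  expect_equal(unname(z[, "rest"]), c(0, 0, 0))
  # columns with variance have mean 0 and sd 1
  expect_equal(mean(z[, "ctcf"]), 0, tolerance = 1e-9)
  expect_equal(sd(z[, "ctcf"]), 1, tolerance = 1e-9)
  expect_error(tf_zscore_matrix(regions[1], tf), "2")
})

test_that("4C-ChIP integration computes per-condition areas, tertiles and log RPM", {
  cmp <- data.frame(
    fragment = paste0("f", 1:6), chrom = "chr1",
    start = (0:5) * 1e4, end = (0:5) * 1e4 + 5000,
    status = c("unchanged", "unchanged", "gained", "lost", "unchanged",
               "gained"),
    control_rpm = c(100, 10, 1, 50, 20, 5),
    experiment_rpm = c(90, 12, 30, NA, 25, 40),
    stringsAsFactors = FALSE)
  flat <- function(v) signal_track("chr1", 0, 1e5, v)
  # flat tracks make every area equal, so the tertile cohort is degenerate
  res <- suppressWarnings(
    integrate_fourc_chip(cmp, k27me3_control = flat(2),
                         k27me3_experiment = flat(1),
                         k27ac_control = flat(0.5),
                         k27ac_experiment = flat(0.5)))
  rec <- res$records
  expect_equal(rec$k27me3_area_control, rep(2 * 5000, 6))
  expect_equal(rec$k27me3_delta, rep(-5000, 6))
  expect_equal(rec$k27ac_delta, rep(0, 6))
  expect_equal(rec$control_rpm_log10[1], 2)  # log10(100)
  expect_true(all(rec$k27me3_tertile == "low"))  # constant cohort
  expect_error(integrate_fourc_chip(cmp, NULL, flat(1), flat(1), flat(1)),
               "track")

  # identical tracks in both conditions give all-zero deltas and ns tests
  res2 <- suppressWarnings(
    integrate_fourc_chip(cmp, flat(1), flat(1), flat(1), flat(1)))
  expect_true(all(res2$records$k27me3_delta == 0))
  expect_true(all(is.na(res2$paired_tests$k27me3_paired_p)))
})

test_that("a planted mark decrease is flagged only in the planted status group", {
  set.seed(521)
  n <- 30
  cmp <- data.frame(
    fragment = paste0("f", 1:n), chrom = "chr1",
    start = (0:(n - 1)) * 2e4, end = (0:(n - 1)) * 2e4 + 8000,
    status = rep(c("unchanged", "gained"), each = n / 2),
    stringsAsFactors = FALSE)
  # control: uniform high K27me3; experiment: halved at unchanged regions only
  runs_start <- (0:(n - 1)) * 2e4
  ctl <- signal_track(rep("chr1", n), runs_start, runs_start + 8000,
                      rep(4, n))
  exp_vals <- ifelse(cmp$status == "unchanged", 1.5, 4) +
    runif(n, -0.1, 0.1)
  expv <- signal_track(rep("chr1", n), runs_start, runs_start + 8000,
                       exp_vals)
  flat <- signal_track("chr1", 0, 6e5, 0.5)
  # uniform control areas again degenerate the tertile cohort (expected)
  res <- suppressWarnings(
    integrate_fourc_chip(cmp, ctl, expv, flat, flat, bin_size = 100))
  pt <- res$paired_tests
  expect_lt(pt$k27me3_paired_p[pt$status == "unchanged"], 0.01)
  expect_gt(pt$k27me3_paired_p[pt$status == "gained"], 0.05)
})
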