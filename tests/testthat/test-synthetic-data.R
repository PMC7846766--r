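# Generators: planted truth construction and reproducibility.

test_that("synthetic genomes are deterministic and validated", {
  g <- make_genome(1, 1e7)
  expect_equal(g$chrom, "chr1")
  expect_equal(g$length, 1e7)
  expect_identical(make_genome(3, c(1e6, 2e6, 3e6), seed = 5),
                   make_genome(3, c(1e6, 2e6, 3e6), seed = 9))
  expect_error(make_genome(1, 0), "length")
})

test_that("planted peak clusters respect the stitching-window geometry", {
  g <- make_genome(1, 1e7)
  pk <- make_peaks_and_signal(g, n_clusters = 5, peaks_per_cluster = 6,
                              n_isolated = 40, seed = 11)
  expect_equal(length(pk$truth$mrr), 5)
  expect_equal(length(pk$peaks), 5 * 6 + 40)
  # within a cluster every gap < window; stitching recovers exactly the truth
  st <- stitch_peaks(pk$peaks, 4000)
  expect_equal(length(st), 5 + 40)
  cl <- st[S4Vectors::mcols(st)$n_constituents > 1]
  expect_equal(gr_to_df(cl), gr_to_df(pk$truth$mrr))
  # elements pairwise separated by more than the window
  d <- gr_to_df(st)
  gaps <- d$start[-1] - d$end[-nrow(d)]
  expect_true(all(gaps >= 4000))
  # identical (parameters, seed) reproduce identical objects
  pk2 <- make_peaks_and_signal(g, n_clusters = 5, peaks_per_cluster = 6,
                               n_isolated = 40, seed = 11)
  expect_identical(gr_to_df(pk$peaks), gr_to_df(pk2$peaks))
  expect_identical(S4Vectors::mcols(pk$treatment)$score,
                   S4Vectors::mcols(pk2$treatment)$score)
  expect_error(make_peaks_and_signal(make_genome(1, 1e5)), "packing")
})

test_that("a negative control plants no truth and recovery is zero", {
  g <- make_genome(1, 1e7)
  pk <- make_peaks_and_signal(g, n_clusters = 0, n_isolated = 120, seed = 7)
  expect_equal(length(pk$truth$mrr), 0)
  called <- call_regions(pk$peaks, pk$treatment, pk$control)
  rich <- called[S4Vectors::mcols(called)$label == "rich"]
  expect_equal(sum(overlaps_any(rich, pk$truth$mrr)), 0)
})

test_that("without signal enrichment planted clusters are not recovered like real ones", {
  g <- make_genome(1, 1e7)
  pk <- make_peaks_and_signal(g, signal_fold = 1, seed = 7)
  called <- call_regions(pk$peaks, pk$treatment, pk$control)
  rich <- called[S4Vectors::mcols(called)$label == "rich"]
  recovered <- sum(overlaps_any(pk$truth$mrr, rich))
  expect_lt(recovered, 18)  # far below the enriched default scenario
})

test_that("interaction generator realizes its planted pair distribution", {
  g <- make_genome(1, 1e7)
  # homogeneous product of marginals: planted log2 ratios all 0
  pref_homog <- c(AA = 0.25, AR = 0.5, RR = 0.25)  # p_A = p_R = 0.5
  ia <- make_interactions(g, c(A = 0.5, R = 0.5), pref_homog, 2000, seed = 3)
  expect_true(all(abs(ia$truth$planted_log2_ratio) < 1e-12))
  # like-like boost: closed-form planted ratios from the preference matrix
  pref <- c(AA = 0.4, AR = 0.2, RR = 0.4)   # marginals 0.5/0.5
  ia2 <- make_interactions(g, c(A = 0.5, R = 0.5), pref, 4000, seed = 3)
  expect_equal(ia2$truth$planted_log2_ratio[ia2$truth$pair == "AA"],
               log2(0.4 / 0.25))
  expect_equal(ia2$truth$planted_log2_ratio[ia2$truth$pair == "AR"],
               log2(0.2 / 0.5))
  # realized pair counts match the planted distribution to rounding
  pe <- pair_enrichment(ia2$state1, ia2$state2)
  expect_equal(pe$observed_prop[match(names(pref), pe$pair)],
               unname(pref), tolerance = 1e-3)
  # anchor states are recoverable from the emitted mark peak sets
  st1 <- assign_anchor_state(anchor_granges(ia2$interactions, 1),
                             ia2$k27ac_peaks, ia2$k27me3_peaks)
  expect_equal(st1, ia2$state1)
  expect_error(make_interactions(g, c(A = 1), c(AA = 1), 0), "interactions")
})

test_that("expression generator spans the specificity extremes", {
  ex_flat <- make_expression(n_genes = 30, alpha = 1e6, seed = 5)
  expect_true(all(ex_flat$truth$specificity < 0.01))
  ex_sharp <- make_expression(n_genes = 30, alpha = 1e-6, seed = 5)
  expect_true(all(ex_sharp$truth$specificity > 0.99))
  # default facet count is 70 (69 reference facets + the cell line)
  ex <- make_expression(n_genes = 10, seed = 2)
  expect_equal(ncol(ex$matrix), 70)
  # truth is the module's own formula on the drawn values: exact
  expect_equal(ex$truth$specificity,
               unname(as.numeric(specificity(ex$matrix))))
  expect_error(make_expression(10, alpha = -1), "concentration")
})

test_that("4C generator plants the distance-dependent change structure", {
  g <- make_genome(2, c(1e7, 5e6))
  # change probability 0: nothing gained or lost
  fc0 <- make_fourc_pair(g, change_range = c(0, 0), seed = 3)
  expect_true(all(fc0$truth$status %in% c("unchanged", "absent") |
                    is.na(fc0$truth$distance_bp)))
  # change probability 1: no cis fragment stays unchanged
  fc1 <- make_fourc_pair(g, change_range = c(1, 1), seed = 3)
  cis1 <- fc1$truth[!is.na(fc1$truth$distance_bp), ]
  expect_false(any(cis1$status == "unchanged"))
  # rising change probability: unchanged proportion decreases over tertiles
  fc <- make_fourc_pair(g, n_fragments = 2000, seed = 5)
  cis <- fc$truth[!is.na(fc$truth$distance_bp) & fc$truth$status != "absent", ]
  ter <- cut(cis$distance_bp, quantile(cis$distance_bp, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("s", "i", "l"))
  prop <- tapply(cis$status == "unchanged", ter, mean)
  expect_true(all(diff(prop) < 0))
  # pooling both conditions recovers the planted status labels exactly
  cmp <- compare_conditions(pool_replicates(fc0$control_reps),
                            pool_replicates(fc0$experiment_reps))
  truth_sub <- fc0$truth[fc0$truth$status != "absent", ]
  expect_setequal(cmp$fragment, truth_sub$fragment)
  m <- merge(cmp, truth_sub, by = "fragment")
  expect_equal(m$status.x, m$status.y)
})

test_that("simulate_full writes a complete, reproducible input bundle", {
  d1 <- withr::local_tempdir()
  res <- simulate_full(d1, seed = 3)
  expected <- c("genome.chrom.sizes", "h3k27me3_peaks.bed",
                "h3k27me3_treatment.bedGraph", "h3k27me3_control.bedGraph",
                "truth_mrr.bed", "loops.bedpe", "k27ac_anchors.bed",
                "k27me3_anchors.bed", "expression.tsv",
                "fourc_control_rep1.tsv", "fourc_control_rep2.tsv",
                "fourc_experiment_rep1.tsv", "fourc_experiment_rep2.tsv",
                "manifest.tsv")
  expect_true(all(file.exists(file.path(d1, expected))))
  # files read back into consistent objects
  genome <- read_chrom_sizes(file.path(d1, "genome.chrom.sizes"))
  expect_equal(genome$chrom, c("chr1", "chr2"))
  peaks <- read_intervals(file.path(d1, "h3k27me3_peaks.bed"), genome)
  expect_equal(length(peaks), length(res$peaks$peaks))
})
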