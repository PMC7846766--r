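# 4C replicate pooling, gained/lost/unchanged classification and distance
# summaries.

make_calls <- function(starts, p, rpm = 10) {
  fourc_calls(rep("chr1", length(starts)), starts, starts + 4000,
              rpm = rep_len(rpm, length(starts)), p_value = p)
}

test_that("pooling unions per-replicate significant fragments at alpha", {
  rep1 <- make_calls(c(0, 10000, 20000), c(0.01, 0.2, 0.04))
  rep2 <- make_calls(c(0, 10000, 20000), c(0.3, 0.3, 0.2))
  pooled <- pool_replicates(list(rep1, rep2))
  # significant in replicate 1 only is still included (union rule)
  expect_setequal(pooled$fragment, c("chr1:0-4000", "chr1:20000-24000"))
  # boundary: p exactly alpha is not significant (strict <)
  repb <- make_calls(30000, 0.05)
  expect_equal(nrow(pool_replicates(list(repb))), 0)
  expect_error(pool_replicates(list(rep1, rep2), baits = c("b1", "b2")),
               "bait")
  # per-replicate RPMs are carried along
  expect_true(all(c("rpm_rep1", "rpm_rep2") %in% names(pooled)))
})

test_that("condition comparison is exact set algebra on fragment keys", {
  ctl <- pool_replicates(list(make_calls(c(0, 1e4, 2e4), c(0.01, 0.01, 0.01))))
  exp <- pool_replicates(list(make_calls(c(1e4, 3e4), c(0.01, 0.01))))
  cmp <- compare_conditions(ctl, exp)
  got <- split(cmp$fragment, cmp$status)
  expect_setequal(got$lost, c("chr1:0-4000", "chr1:20000-24000"))
  expect_equal(got$unchanged, "chr1:10000-14000")
  expect_equal(got$gained, "chr1:30000-34000")
  # identical sets are all unchanged
  cmp2 <- compare_conditions(ctl, ctl)
  expect_true(all(cmp2$status == "unchanged"))
})

test_that("fuzzed comparisons satisfy the partition and swap dualities", {
  set.seed(401)
  for (rep in 1:25) {
    s_all <- sample(seq(0, 1e6, by = 5000))
    a <- sort(sample(s_all, 30)); b <- sort(sample(s_all, 30))
    ctl <- pool_replicates(list(make_calls(a, rep(0.01, 30))))
    exp <- pool_replicates(list(make_calls(b, rep(0.01, 30))))
    cmp <- compare_conditions(ctl, exp)
    # statuses partition the union
    expect_equal(nrow(cmp), length(union(ctl$fragment, exp$fragment)))
    expect_equal(sum(cmp$status == "gained") + sum(cmp$status == "lost") +
                   sum(cmp$status == "unchanged"), nrow(cmp))
    # independent set-algebra oracle
    expect_setequal(cmp$fragment[cmp$status == "gained"],
                    setdiff(exp$fragment, ctl$fragment))
    expect_setequal(cmp$fragment[cmp$status == "lost"],
                    setdiff(ctl$fragment, exp$fragment))
    # swapping conditions swaps gained and lost
    swp <- compare_conditions(exp, ctl)
    expect_setequal(swp$fragment[swp$status == "gained"],
                    cmp$fragment[cmp$status == "lost"])
    expect_setequal(swp$fragment[swp$status == "unchanged"],
                    cmp$fragment[cmp$status == "unchanged"])
  }
})

test_that("bait distances use midpoints, tertiles and a trans flag", {
  # 9 cis fragments at 1..9 Mb from the bait
  starts <- 1:9 * 1e6
  ctl <- pool_replicates(list(make_calls(starts, rep(0.01, 9))))
  exp <- pool_replicates(list(make_calls(starts[1:5], rep(0.01, 5))))
  cmp <- compare_conditions(ctl, exp)
  cmp <- rbind(cmp, data.frame(fragment = "chr9:0-4000", chrom = "chr9",
                               start = 0, end = 4000, status = "gained",
                               control_rpm = NA, experiment_rpm = NA))
  bd <- bait_distance(cmp, "chr1", 0, 4000)
  cis <- bd[bd$chrom == "chr1", ]
  expect_equal(sort(cis$distance_bp), starts)  # midpoint minus bait midpoint
  expect_equal(as.integer(table(cis$distance_category)[c("short",
                                                         "intermediate",
                                                         "long")]),
               c(3L, 3L, 3L))
  expect_equal(cis$distance_category[order(cis$distance_bp)],
               rep(c("short", "intermediate", "long"), each = 3))
  expect_equal(bd$distance_category[bd$chrom == "chr9"], "trans")
  expect_true(is.na(bd$distance_bp[bd$chrom == "chr9"]))
  # zero distance is short
  bd0 <- bait_distance(cmp[1:3, ], "chr1", 1e6, 1e6 + 4000)
  expect_equal(bd0$distance_category[bd0$distance_bp == 0], "short")
})

test_that("tertile category counts differ by at most one for distinct distances", {
  set.seed(411)
  for (rep in 1:10) {
    n <- sample(6:40, 1)
    starts <- sample(seq(1e5, 9e6, by = 1e4), n)
    ctl <- pool_replicates(list(make_calls(starts, rep(0.01, n))))
    cmp <- bait_distance(compare_conditions(ctl, ctl), "chr1", 0, 4000)
    counts <- table(cmp$distance_category)
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("proportion unchanged drops sparse categories", {
  df <- data.frame(
    fragment = paste0("f", 1:8), chrom = "chr1", start = 1:8, end = 2:9,
    status = c("unchanged", "unchanged", "gained",
               "unchanged", "lost", "unchanged", "gained", "lost"),
    distance_category = c(rep("short", 3), rep("intermediate", 3),
                          "long", "long"),
    stringsAsFactors = FALSE)
  pu <- proportion_unchanged(df)
  expect_equal(pu$proportion[pu$distance_category == "short"], 2 / 3)
  expect_equal(pu$proportion[pu$distance_category == "intermediate"], 2 / 3)
  expect_false("long" %in% pu$distance_category)  # only 2 fragments
  expect_equal(attr(pu, "excluded"), "long")
})

test_that("distance summaries separate changed from unchanged loops", {
  df <- data.frame(
    fragment = paste0("f", 1:5), chrom = "chr1",
    start = c(1, 2, 3, 10, 20) * 1e6, end = c(1, 2, 3, 10, 20) * 1e6 + 1,
    status = c("unchanged", "unchanged", "unchanged", "gained", "lost"),
    stringsAsFactors = FALSE)
  bd <- bait_distance(df, "chr1", 0, 1)
  ds <- distance_summary(bd)
  expect_equal(ds$summary$mean_bp[ds$summary$group == "changed"], 15e6)
  expect_equal(ds$summary$mean_bp[ds$summary$group == "unchanged"], 2e6)
  # single-group input reports the other group empty
  ds1 <- distance_summary(bd[bd$status == "unchanged", ])
  expect_equal(ds1$summary$n[ds1$summary$group == "changed"], 0)
  expect_true(is.na(ds1$wilcox_p))
})
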