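# Differential 4C-seq loop analysis: pool replicate significant-interaction
# calls, classify fragments between conditions as gained/lost/unchanged,
# and summarize by distance to the bait.

#' Build a 4C call table for one replicate
#'
#' @param chrom,start0,end0 restriction-fragment coordinates (BED 0-based).
#' @param rpm reads per million at the fragment.
#' @param p_value significance of the interaction call in \[0, 1\].
#' @return data.frame with a `fragment` key column `chrom:start-end`.
#' @export
fourc_calls <- function(chrom, start0, end0, rpm, p_value) {
  if (any(p_value < 0 | p_value > 1)) stop("p_value outside [0, 1]")
  if (any(rpm < 0)) stop("negative RPM")
  if (any(start0 >= end0)) stop("invalid fragment interval(s)")
  data.frame(chrom = as.character(chrom), start = as.numeric(start0),
             end = as.numeric(end0), rpm = as.numeric(rpm),
             p_value = as.numeric(p_value),
             fragment = paste0(chrom, ":", start0, "-", end0),
             stringsAsFactors = FALSE)
}

#' Read a 4C call table (chrom, start, end, rpm, p_value TSV)
#' @param path tab-delimited file, with or without a header line.
#' @return data.frame as from [fourc_calls()].
#' @export
read_fourc_calls <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("4C call table needs 5 columns")
  fourc_calls(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]])
}

#' Pool replicate 4C calls into a condition-level significant set
#'
#' A fragment is significant in a replicate iff p < alpha; the pooled set is
#' the union over replicates, keyed by exact fragment coordinates. Per-
#' replicate RPMs are carried along (NA where a replicate did not report the
#' fragment).
#'
#' @param replicates list of call tables (from [fourc_calls()]).
#' @param alpha significance cut-off; default 0.05.
#' @param baits optional character vector of bait identifiers, one per
#'   replicate; inconsistent baits are an error.
#' @return data.frame: fragment key, chrom/start/end, rpm.rep1...,
#'   mean_rpm.
#' @export
pool_replicates <- function(replicates, alpha = 0.05, baits = NULL) {
  if (length(replicates) < 1) stop("need >= 1 replicate")
  if (!is.null(baits) && length(unique(baits)) > 1)
    stop("inconsistent bait across replicates: ",
         paste(unique(baits), collapse = " vs "))
  sig <- lapply(replicates, function(r) r[r$p_value < alpha, , drop = FALSE])
  frags <- unique(do.call(rbind, lapply(sig, function(r)
    r[, c("fragment", "chrom", "start", "end")])))
  if (is.null(frags) || nrow(frags) == 0)
    frags <- data.frame(fragment = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  rownames(frags) <- NULL
  for (i in seq_along(replicates)) {
    r <- replicates[[i]]
    frags[[paste0("rpm_rep", i)]] <-
      r$rpm[match(frags$fragment, r$fragment)]
  }
  rpm_cols <- grep("^rpm_rep", names(frags))
  frags$mean_rpm <- rowMeans(frags[, rpm_cols, drop = FALSE], na.rm = TRUE)
  frags$mean_rpm[is.nan(frags$mean_rpm)] <- NA_real_
  frags
}

#' Compare pooled 4C sets between conditions
#'
#' Gained: present only in the experiment condition; lost: only in the
#' control condition; unchanged: present in both. Exact set algebra on
#' fragment coordinate keys; the statuses partition the union.
#'
#' @param control_set,experiment_set pooled sets from [pool_replicates()].
#' @return data.frame over the union of fragments: fragment, chrom, start,
#'   end, status, control/experiment mean RPM.
#' @export
compare_conditions <- function(control_set, experiment_set) {
  keys <- union(control_set$fragment, experiment_set$fragment)
  in_c <- keys %in% control_set$fragment
  in_e <- keys %in% experiment_set$fragment
  status <- ifelse(in_c & in_e, "unchanged", ifelse(in_e, "gained", "lost"))
  src <- rbind(control_set[, c("fragment", "chrom", "start", "end")],
               experiment_set[, c("fragment", "chrom", "start", "end")])
  src <- src[!duplicated(src$fragment), , drop = FALSE]
  ix <- match(keys, src$fragment)
  data.frame(fragment = keys, chrom = src$chrom[ix], start = src$start[ix],
             end = src$end[ix], status = status,
             control_rpm = control_set$mean_rpm[match(keys, control_set$fragment)],
             experiment_rpm = experiment_set$mean_rpm[match(keys, experiment_set$fragment)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bait distances and distance tertiles
#'
#' Distance is |fragment midpoint - bait midpoint| for fragments on the
#' bait's chromosome; trans fragments are flagged and excluded from the
#' distance categories. Categories are balanced rank tertiles (short /
#' intermediate / long) of the cis distances over the comparison's union
#' set: the sorted distances are split into three contiguous groups whose
#' sizes differ by at most one (equal to the interpolated-quantile split
#' whenever n is divisible by 3).
#'
#' @param comparison data.frame from [compare_conditions()].
#' @param bait_chrom,bait_start0,bait_end0 bait fragment coordinates.
#' @return `comparison` with `distance_bp` (NA for trans) and
#'   `distance_category` ("short"/"intermediate"/"long"/"trans") columns.
#' @export
bait_distance <- function(comparison, bait_chrom, bait_start0, bait_end0) {
  bait_mid <- (bait_start0 + bait_end0) / 2
  cis <- comparison$chrom == bait_chrom
  mid <- (comparison$start + comparison$end) / 2
  comparison$distance_bp <- ifelse(cis, abs(mid - bait_mid), NA_real_)
  comparison$distance_category <- rep("trans", nrow(comparison))
  if (any(cis)) {
    d <- comparison$distance_bp[cis]
    n <- length(d)
    if (n >= 3) {
      k <- n %/% 3; r <- n %% 3
      sizes <- c(k + (r >= 1), k + (r >= 2), k)  # short, intermediate, long
      lab <- rep(c("short", "intermediate", "long"), times = sizes)
      comparison$distance_category[cis] <-
        lab[rank(d, ties.method = "first")]
    } else {
      comparison$distance_category[cis] <- "short"
    }
  }
  comparison
}

#' Proportion of unchanged 4C interactions per distance category
#'
#' unchanged / total per category; categories holding fewer than 3
#' interactions are excluded (noted in the `excluded` attribute).
#'
#' @param comparison output of [bait_distance()].
#' @return data.frame: distance_category, n_total, n_unchanged, proportion.
#' @export
proportion_unchanged <- function(comparison) {
  cats <- c("short", "intermediate", "long")
  df <- comparison[comparison$distance_category %in% cats, , drop = FALSE]
  out <- do.call(rbind, lapply(cats, function(cc) {
    sub <- df[df$distance_category == cc, , drop = FALSE]
    data.frame(distance_category = cc, n_total = nrow(sub),
               n_unchanged = sum(sub$status == "unchanged"),
               proportion = if (nrow(sub) > 0)
                 sum(sub$status == "unchanged") / nrow(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  excluded <- out$distance_category[out$n_total < 3]
  out <- out[out$n_total >= 3, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Distance statistics for changed vs unchanged loops
#'
#' Changed = gained plus lost. Cis distances only; reports means and
#' medians per group plus a rank-based (Wilcoxon) two-sample comparison.
#'
#' @param comparison output of [bait_distance()].
#' @return list: `summary` data.frame (group, n, mean_bp, median_bp) and
#'   `wilcox_p` (NA when either group is empty).
#' @export
distance_summary <- function(comparison) {
  cis <- comparison[!is.na(comparison$distance_bp), , drop = FALSE]
  if (nrow(cis) == 0) stop("no cis fragments")
  grp <- ifelse(cis$status == "unchanged", "unchanged", "changed")
  summ <- do.call(rbind, lapply(c("changed", "unchanged"), function(g) {
    d <- cis$distance_bp[grp == g]
    data.frame(group = g, n = length(d),
               mean_bp = if (length(d)) mean(d) else NA_real_,
               median_bp = if (length(d)) stats::median(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  p <- if (all(c("changed", "unchanged") %in% grp)) {
    stats::wilcox.test(cis$distance_bp[grp == "changed"],
                       cis$distance_bp[grp == "unchanged"],
                       exact = FALSE)$p.value
  } else NA_real_
  list(summary = summ, wilcox_p = p)
}
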