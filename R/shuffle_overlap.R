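# Same-chromosome randomization of region sets and the permutation overlap
# test used to compare called regions against external element lists (e.g.
# a silencer-screen list).

#' Randomly relocate each region on its own chromosome
#'
#' Each region keeps its chromosome and length; the new start is uniform on
#' \[0, L - len\] (BED coordinates). Regions are placed independently, so
#' shuffled regions may overlap each other and the original position.
#'
#' @param regions `GRanges`.
#' @param genome genome table; every region must fit its chromosome.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return `GRanges` of shuffled regions (same order, chroms and widths).
#' @export
shuffle_same_chromosome <- function(regions, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- .seqlengths_of(genome)
  chr <- as.character(GenomicRanges::seqnames(regions))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    stop("chromosomes absent from genome table: ",
         paste(unknown, collapse = ", "))
  len <- GenomicRanges::width(regions)
  L <- sl[chr]
  if (any(len > L))
    stop("region longer than its chromosome")
  # floor(runif * (slots)) over starts 0..L-len, in BED coordinates
  new_start0 <- floor(stats::runif(length(regions)) * (L - len + 1))
  new_start0 <- pmin(new_start0, L - len)  # guard the runif upper edge
  GenomicRanges::GRanges(chr, IRanges::IRanges(start = new_start0 + 1,
                                               width = len))
}

#' Percentage of target elements overlapped by a query set
#'
#' @param target `GRanges` (non-empty): the external element list.
#' @param query `GRanges`: e.g. MRRs or typical H3K27me3 regions.
#' @return 100 * (number of target elements with >= 1 bp overlap with any
#'   query element) / (number of target elements).
#' @export
overlap_percentage <- function(target, query) {
  if (length(target) == 0) stop("empty target set")
  100 * sum(overlaps_any(target, query)) / length(target)
}

#' Permutation overlap test by same-chromosome shuffling
#'
#' Shuffles the query set `n_shuffles` times, recomputing the overlap
#' percentage each time, and tests whether the expected overlap is lower
#' than the actual with a one-sided one-sample t-test
#' (`t.test(expected, mu = actual, alternative = "less")`); the empirical
#' permutation p-value `(1 + #\{expected >= actual\}) / (n_shuffles + 1)` is
#' reported alongside as the statistically safer headline.
#'
#' @param target `GRanges` element list whose overlap fraction is measured.
#' @param query `GRanges` region set to be shuffled.
#' @param genome genome table.
#' @param n_shuffles number of shuffles (>= 2); default 1000.
#' @param seed integer seed.
#' @return list of class `shuffle_test`: `actual_pct`, `expected_pcts`,
#'   `p_value` (t-test; NA with a warning if the shuffled percentages are
#'   constant), `empirical_p`, `n_shuffles`.
#' @export
permutation_overlap_test <- function(target, query, genome,
                                     n_shuffles = 1000, seed = 1) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  actual <- overlap_percentage(target, query)
  set.seed(seed)
  # all shuffles drawn in one batch and resolved with a single overlap
  # query, replicate-major so each replicate is an independent shuffle
  sl <- .seqlengths_of(genome)
  chr <- as.character(GenomicRanges::seqnames(query))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    stop("chromosomes absent from genome table: ",
         paste(unknown, collapse = ", "))
  len <- GenomicRanges::width(query)
  L <- sl[chr]
  if (any(len > L)) stop("region longer than its chromosome")
  nq <- length(query)
  rep_id <- rep(seq_len(n_shuffles), each = nq)
  u <- stats::runif(n_shuffles * nq)
  new_start0 <- pmin(floor(u * rep(L - len + 1, n_shuffles)),
                     rep(L - len, n_shuffles))
  big <- GenomicRanges::GRanges(rep(chr, n_shuffles),
                                IRanges::IRanges(start = new_start0 + 1,
                                                 width = rep(len, n_shuffles)))
  hits <- GenomicRanges::findOverlaps(target, big)
  hit_pairs <- unique(data.frame(
    t = S4Vectors::queryHits(hits),
    r = rep_id[S4Vectors::subjectHits(hits)]))
  per_rep <- tabulate(hit_pairs$r, nbins = n_shuffles)
  expected <- 100 * per_rep / length(target)
  p_t <- if (stats::sd(expected) == 0) {
    warning("zero variance among shuffled overlap percentages; ",
            "t-test undefined, reporting empirical p only")
    NA_real_
  } else {
    stats::t.test(expected, mu = actual, alternative = "less")$p.value
  }
  emp <- (1 + sum(expected >= actual)) / (n_shuffles + 1)
  res <- list(actual_pct = actual, expected_pcts = expected,
              p_value = p_t, empirical_p = emp, n_shuffles = n_shuffles)
  class(res) <- "shuffle_test"
  res
}
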