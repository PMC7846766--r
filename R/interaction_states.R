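# Chromatin-state annotation of interaction anchors and observed/expected
# state-pair enrichment under the marginal homogeneous pairing model.

#' Assign A/R/B/Q chromatin states to anchors
#'
#' A (active): overlap only H3K27ac peaks; R (repressive): only H3K27me3;
#' B (both); Q (quiescent): neither. Overlap is >= 1 bp.
#'
#' @param anchors `GRanges`.
#' @param k27ac_peaks,k27me3_peaks `GRanges` peak sets.
#' @return character vector of states along `anchors`.
#' @export
assign_anchor_state <- function(anchors, k27ac_peaks, k27me3_peaks) {
  ac <- overlaps_any(anchors, k27ac_peaks)
  me <- overlaps_any(anchors, k27me3_peaks)
  ifelse(ac & me, "B", ifelse(ac, "A", ifelse(me, "R", "Q")))
}

#' Assign T/MRR repressive classes to anchors
#'
#' MRR takes precedence over typical (T); anchors overlapping neither are
#' "none" and are excluded from the T/MRR enrichment analysis.
#'
#' @param anchors `GRanges`.
#' @param mrr_regions,typical_regions `GRanges` from the MRR caller.
#' @return character vector in {"MRR", "T", "none"}.
#' @export
assign_repressive_class <- function(anchors, mrr_regions, typical_regions) {
  m <- overlaps_any(anchors, mrr_regions)
  t <- overlaps_any(anchors, typical_regions)
  ifelse(m, "MRR", ifelse(t, "T", "none"))
}

# canonical unordered pair key, e.g. "AR" for states A,R in either order
.pair_key <- function(s1, s2) {
  paste0(pmin(s1, s2), pmax(s1, s2))
}

#' Observed vs expected state-pair enrichment
#'
#' Anchor-state marginals are counted over anchor slots (each interaction
#' contributes two); the expected proportion of an unordered pair (s, t)
#' under independent homogeneous pairing is 2*p_s*p_t for s != t and p_s^2
#' for s == t. log2(observed/expected) is NA (flagged) when a pair is
#' unobserved; no pseudocount is applied unless `epsilon > 0`.
#'
#' @param state1,state2 character vectors of anchor states (parallel).
#' @param unique_loci optional `GRanges` pair (list of anchor1, anchor2) --
#'   when supplied with `marginals = "loci"`, marginals are counted over
#'   unique anchor positions instead of slots.
#' @param marginals "slots" (default) or "loci".
#' @param epsilon optional smoothing added to observed and expected
#'   proportions before the ratio (default 0).
#' @return A data.frame: pair, observed_count, observed_prop, expected_prop,
#'   log2_ratio; anchor-state marginals attached as attribute `marginals`.
#' @export
pair_enrichment <- function(state1, state2, unique_loci = NULL,
                            marginals = c("slots", "loci"), epsilon = 0) {
  marginals <- match.arg(marginals)
  n <- length(state1)
  if (n == 0 || length(state2) != n) stop("need >= 1 interaction with two states each")
  states <- sort(unique(c(state1, state2)))
  if (marginals == "slots") {
    slot_states <- c(state1, state2)
    p <- table(factor(slot_states, levels = states)) / (2 * n)
  } else {
    if (is.null(unique_loci)) stop("marginals = 'loci' needs unique_loci anchors")
    all_anchors <- c(unique_loci[[1]], unique_loci[[2]])
    all_states <- c(state1, state2)
    key <- paste0(as.character(GenomicRanges::seqnames(all_anchors)), ":",
                  GenomicRanges::start(all_anchors), "-",
                  GenomicRanges::end(all_anchors))
    keep <- !duplicated(key)
    p <- table(factor(all_states[keep], levels = states)) / sum(keep)
  }
  p <- as.numeric(p); names(p) <- states
  # enumerate unordered pairs including diagonals, in lexicographic order
  grid <- expand.grid(t = states, s = states, stringsAsFactors = FALSE)
  grid <- grid[grid$s <= grid$t, c("s", "t"), drop = FALSE]
  pair_keys <- paste0(grid$s, grid$t)
  o <- order(pair_keys)
  grid <- grid[o, , drop = FALSE]
  pair_keys <- pair_keys[o]
  obs_keys <- .pair_key(state1, state2)
  obs_count <- as.integer(table(factor(obs_keys, levels = pair_keys)))
  obs_prop <- obs_count / n
  exp_prop <- ifelse(grid$s == grid$t, p[grid$s]^2, 2 * p[grid$s] * p[grid$t])
  exp_prop <- as.numeric(exp_prop)
  num <- obs_prop + epsilon
  den <- exp_prop + epsilon
  log2_ratio <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
  out <- data.frame(pair = pair_keys, observed_count = obs_count,
                    observed_prop = obs_prop, expected_prop = exp_prop,
                    log2_ratio = log2_ratio, stringsAsFactors = FALSE)
  attr(out, "marginals") <- p
  attr(out, "n_interactions") <- n
  out
}

#' Interaction density at constituent peaks, with shuffled-size controls
#'
#' Counts, per constituent peak, interactions with at least one anchor
#' overlapping it. Control regions are built by expanding the midpoint of
#' each constituent to the global median constituent length, then placing
#' each uniformly at random on its own chromosome; this is repeated
#' `shuffles` times.
#'
#' @param constituents `GRanges` of constituent peaks (non-empty).
#' @param interactions `interaction_set`.
#' @param genome genome table bounding random placement.
#' @param shuffles number of shuffled control replicates (>= 1).
#' @param seed integer seed.
#' @return list with `observed` (integer vector per constituent),
#'   `control` (matrix constituents x shuffles) and `control_width` (the
#'   median constituent length used).
#' @export
constituent_interaction_density <- function(constituents, interactions,
                                            genome, shuffles = 1,
                                            seed = 1) {
  if (length(constituents) == 0) stop("no constituent peaks")
  if (shuffles < 1) stop("shuffles must be >= 1")
  a1 <- anchor_granges(interactions, 1)
  a2 <- anchor_granges(interactions, 2)
  count_hits <- function(regions) {
    GenomicRanges::countOverlaps(regions, a1) +
      GenomicRanges::countOverlaps(regions, a2) -
      # an interaction with both anchors on the region counts once
      .pair_hits(regions, a1, a2)
  }
  observed <- count_hits(constituents)
  w <- round(stats::median(GenomicRanges::width(constituents)))
  mid <- floor((GenomicRanges::start(constituents) +
                  GenomicRanges::end(constituents)) / 2)
  expanded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(constituents),
    IRanges::IRanges(start = mid - floor(w / 2), width = w))
  set.seed(seed)
  control <- matrix(0L, nrow = length(constituents), ncol = shuffles)
  for (j in seq_len(shuffles)) {
    shuf <- shuffle_same_chromosome(expanded, genome, seed = NULL)
    control[, j] <- count_hits(shuf)
  }
  list(observed = observed, control = control, control_width = w)
}

# number of interactions with BOTH anchors overlapping each region
.pair_hits <- function(regions, a1, a2) {
  h1 <- GenomicRanges::findOverlaps(regions, a1)
  h2 <- GenomicRanges::findOverlaps(regions, a2)
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  both <- k1 %in% k2
  out <- integer(length(regions))
  if (any(both)) {
    tab <- table(S4Vectors::queryHits(h1)[both])
    out[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}
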