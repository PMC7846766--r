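# Synthetic-data generators. Every pipeline input can be generated here
# with planted ground truth, so each stage (and the full workflow) is
# testable without any external download. A single seed fans out to
# independent per-generator substreams.

# deterministic substream seed, kept inside 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483629 + 1)
}

#' Deterministic synthetic genome table
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths in bp (recycled to `n_chrom`).
#' @param seed kept for interface symmetry; the table is deterministic.
#' @return genome table with chromosomes chr1..chrN.
#' @export
make_genome <- function(n_chrom = 1, lengths = 1e7, seed = 1) {
  lengths <- rep_len(lengths, n_chrom)
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  genome_table(paste0("chr", seq_len(n_chrom)), lengths)
}

#' Synthetic ChIP-seq peaks and coverage with planted rich clusters
#'
#' Plants `n_clusters` clusters of high-signal peaks (intra-cluster gaps
#' below the stitching window, so each cluster stitches into one region)
#' plus `n_isolated` single low-signal peaks, all separated by more than
#' `window` bp. Treatment coverage is Poisson per `bin` bp: mean
#' `background` outside peaks, `background * signal_fold` inside cluster
#' peaks and `background * signal_fold / 3` inside isolated peaks; the
#' control track is flat at `background`.
#'
#' @param genome genome table (elements are packed onto chromosome 1).
#' @param n_clusters planted rich clusters (the ground-truth MRRs).
#' @param peaks_per_cluster constituent peaks per cluster.
#' @param n_isolated isolated low-signal peaks.
#' @param signal_fold treatment enrichment of cluster peaks over background.
#' @param background Poisson mean of the background coverage per bin.
#' @param window stitching window the layout must respect (default 4000).
#' @param intra_gap_range range of intra-cluster gaps (must stay < window).
#' @param peak_width_range range of peak widths, bp.
#' @param bin coverage resolution in bp (default 10).
#' @param seed integer seed.
#' @return list: `peaks` (`GRanges`), `treatment`, `control` (signal
#'   tracks), `truth` (list with `mrr` cluster spans as `GRanges`,
#'   `isolated` peak `GRanges`, and the parameters).
#' @export
make_peaks_and_signal <- function(genome, n_clusters = 20,
                                  peaks_per_cluster = 8, n_isolated = 500,
                                  signal_fold = 10, background = 1,
                                  window = 4000,
                                  intra_gap_range = c(500, 3000),
                                  peak_width_range = c(150, 500),
                                  bin = 10, seed = 1) {
  if (max(intra_gap_range) >= window)
    stop("intra-cluster gaps must stay below the stitching window")
  set.seed(.sub_seed(seed, 1))
  chrom <- genome$chrom[1]
  L <- genome$length[1]
  n_el <- n_clusters + n_isolated
  if (n_el == 0) stop("nothing to plant")
  # element layouts: a cluster is a run of peaks with gaps < window
  rwid <- function(n) round(stats::runif(n, peak_width_range[1],
                                         peak_width_range[2]))
  rgap <- function(n) round(stats::runif(n, intra_gap_range[1],
                                         intra_gap_range[2]))
  kind <- sample(c(rep("cluster", n_clusters), rep("isolated", n_isolated)))
  layouts <- lapply(kind, function(k) {
    if (k == "cluster") {
      w <- rwid(peaks_per_cluster)
      g <- rgap(peaks_per_cluster - 1)
      off <- cumsum(c(0, w[-peaks_per_cluster] + g))
      list(kind = k, rel_start = off, width = w, span = off[peaks_per_cluster] +
             w[peaks_per_cluster])
    } else {
      w <- rwid(1)
      list(kind = k, rel_start = 0, width = w, span = w)
    }
  })
  spans <- vapply(layouts, function(x) x$span, numeric(1))
  min_gap <- window + 2 * bin  # keep neighbours un-stitchable
  free <- L - sum(spans) - (n_el + 1) * min_gap
  if (free < 0) stop("infeasible packing: elements do not fit the chromosome")
  extra <- stats::runif(n_el + 1)
  extra <- floor(extra / sum(extra) * free)
  gaps <- min_gap + extra
  pos <- cumsum(c(gaps[1], spans[-n_el] + gaps[-c(1, n_el + 1)]))
  # assemble peaks (BED coordinates)
  pk <- do.call(rbind, lapply(seq_len(n_el), function(i) {
    lay <- layouts[[i]]
    data.frame(start = pos[i] + lay$rel_start,
               end = pos[i] + lay$rel_start + lay$width,
               kind = lay$kind, element = i, stringsAsFactors = FALSE)
  }))
  peaks <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pk$start + 1, pk$end))
  S4Vectors::mcols(peaks)$name <- paste0("peak_", seq_len(nrow(pk)))
  S4Vectors::mcols(peaks)$kind <- pk$kind
  # planted MRR = span of each cluster
  cl <- pk[pk$kind == "cluster", , drop = FALSE]
  truth_mrr <- if (nrow(cl)) {
    agg_s <- tapply(cl$start, cl$element, min)
    agg_e <- tapply(cl$end, cl$element, max)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(as.numeric(agg_s) + 1,
                                                   as.numeric(agg_e)))
  } else GenomicRanges::GRanges()
  iso <- pk[pk$kind == "isolated", , drop = FALSE]
  truth_iso <- if (nrow(iso))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(iso$start + 1, iso$end))
  else GenomicRanges::GRanges()
  # Poisson coverage at `bin` bp resolution
  n_bins <- ceiling(L / bin)
  bin_start <- (seq_len(n_bins) - 1) * bin
  lambda <- rep(background, n_bins)
  mark_bins <- function(s0, e0, value) {
    for (i in seq_along(s0)) {
      b0 <- floor(s0[i] / bin) + 1
      b1 <- ceiling(e0[i] / bin)
      lambda[b0:b1] <<- value
    }
  }
  if (nrow(cl)) mark_bins(cl$start, cl$end, background * signal_fold)
  if (nrow(iso)) mark_bins(iso$start, iso$end, background * signal_fold / 3)
  values <- stats::rpois(n_bins, lambda)
  keep <- values > 0
  bs <- bin_start[keep]
  treatment <- signal_track(rep(chrom, length(bs)), bs, pmin(bs + bin, L),
                            values[keep])
  control <- signal_track(chrom, 0, L, background)
  list(peaks = peaks, treatment = treatment, control = control,
       truth = list(mrr = truth_mrr, isolated = truth_iso,
                    params = list(n_clusters = n_clusters,
                                  peaks_per_cluster = peaks_per_cluster,
                                  n_isolated = n_isolated,
                                  signal_fold = signal_fold,
                                  background = background, window = window,
                                  bin = bin, seed = seed)))
}

#' Synthetic state-labelled loop list with a planted pair distribution
#'
#' Places `n_anchors` non-overlapping anchors, assigns them chromatin
#' states with probabilities `state_probs`, and draws `n_interactions`
#' whose unordered state-pair counts follow the planted `pair_preference`
#' distribution (largest-remainder allocation of n * preference plus a
#' multinomial draw of the remainder, so the realized pair distribution
#' matches the planted one to within rounding). Mark peak sets covering the
#' anchors are emitted so the states are recoverable by overlap.
#'
#' @param genome genome table.
#' @param state_probs named probabilities of anchor states (used to
#'   provision anchors per state), e.g. c(A=.3, R=.3, B=.1, Q=.3).
#' @param pair_preference named probabilities over unordered pairs (names
#'   like "AR" with letters sorted); must sum to 1.
#' @param n_interactions number of loops.
#' @param n_anchors number of distinct anchors to place.
#' @param anchor_width anchor width in bp (default 2000).
#' @param seed integer seed.
#' @return list: `interactions` (`interaction_set`), `state1`/`state2`,
#'   `anchors` (`GRanges` with `state`), `k27ac_peaks`, `k27me3_peaks`,
#'   `truth` (data.frame pair / planted_prop / planted_log2_ratio).
#' @export
make_interactions <- function(genome, state_probs, pair_preference,
                              n_interactions, n_anchors = 2000,
                              anchor_width = 2000, seed = 1) {
  if (n_interactions < 1) stop("n_interactions must be >= 1")
  if (abs(sum(pair_preference) - 1) > 1e-8)
    stop("pair_preference must sum to 1")
  set.seed(.sub_seed(seed, 2))
  states <- names(state_probs)
  # provision anchors per state, at least 2 per state present in pairs
  n_per <- pmax(2, round(state_probs / sum(state_probs) * n_anchors))
  anchor_states <- rep(states, n_per)
  n_anchors <- length(anchor_states)
  anchor_states <- sample(anchor_states)
  # non-overlapping placement: even grid with >= anchor_width spacing
  L <- genome$length[1]
  slot <- anchor_width * 2
  if (n_anchors * slot > L) stop("anchors do not fit the chromosome")
  starts0 <- (seq_len(n_anchors) - 1) * slot +
    floor(stats::runif(n_anchors) * (slot - anchor_width))
  anchors <- GenomicRanges::GRanges(genome$chrom[1],
                                    IRanges::IRanges(starts0 + 1,
                                                     starts0 + anchor_width))
  S4Vectors::mcols(anchors)$state <- anchor_states
  # planted pair counts: floor(n * p), remainder by multinomial
  p <- pair_preference
  cnt <- floor(n_interactions * p)
  rem <- n_interactions - sum(cnt)
  if (rem > 0) {
    resid <- n_interactions * p - cnt
    add <- stats::rmultinom(1, rem, prob = if (sum(resid) > 0) resid else p)
    cnt <- cnt + as.numeric(add)
  }
  idx_by_state <- split(seq_len(n_anchors), anchor_states)
  s1 <- character(0); s2 <- character(0); i1 <- integer(0); i2 <- integer(0)
  for (k in seq_along(cnt)) {
    m <- cnt[k]
    if (m == 0) next
    a <- substr(names(p)[k], 1, 1); b <- substr(names(p)[k], 2, 2)
    ia <- sample(idx_by_state[[a]], m, replace = TRUE)
    ib <- sample(idx_by_state[[b]], m, replace = TRUE)
    same <- ia == ib
    while (any(same)) {  # anchors of a loop must differ
      ib[same] <- sample(idx_by_state[[b]], sum(same), replace = TRUE)
      same <- ia == ib
    }
    i1 <- c(i1, ia); i2 <- c(i2, ib)
    s1 <- c(s1, rep(a, m)); s2 <- c(s2, rep(b, m))
  }
  o <- sample(length(i1))  # shuffle record order
  i1 <- i1[o]; i2 <- i2[o]; s1 <- s1[o]; s2 <- s2[o]
  ix <- interaction_set(
    as.character(GenomicRanges::seqnames(anchors))[i1],
    GenomicRanges::start(anchors)[i1] - 1, GenomicRanges::end(anchors)[i1],
    as.character(GenomicRanges::seqnames(anchors))[i2],
    GenomicRanges::start(anchors)[i2] - 1, GenomicRanges::end(anchors)[i2],
    dedup = FALSE)
  # planted log2(obs/exp) from the preference matrix itself
  slot_marg <- vapply(states, function(s) {
    sum(vapply(seq_along(p), function(k) {
      a <- substr(names(p)[k], 1, 1); b <- substr(names(p)[k], 2, 2)
      p[k] * ((a == s) + (b == s))
    }, numeric(1))) / 2
  }, numeric(1))
  truth <- do.call(rbind, lapply(seq_along(p), function(k) {
    a <- substr(names(p)[k], 1, 1); b <- substr(names(p)[k], 2, 2)
    e <- if (a == b) slot_marg[a]^2 else 2 * slot_marg[a] * slot_marg[b]
    data.frame(pair = names(p)[k], planted_prop = as.numeric(p[k]),
               expected_prop = as.numeric(e),
               planted_log2_ratio = if (p[k] > 0) log2(p[k] / e) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  mark_of <- S4Vectors::mcols(anchors)$state
  k27ac <- anchors[mark_of %in% c("A", "B")]
  k27me3 <- anchors[mark_of %in% c("R", "B")]
  list(interactions = ix, state1 = s1, state2 = s2, anchors = anchors,
       k27ac_peaks = GenomicRanges::granges(k27ac),
       k27me3_peaks = GenomicRanges::granges(k27me3),
       truth = truth)
}

#' Synthetic gene-by-facet expression with known specificity
#'
#' Per gene, the facet profile is a symmetric Dirichlet(alpha) draw scaled
#' by a lognormal total; the true specificity is the module's own formula
#' applied to the drawn values (hence exact).
#'
#' @param n_genes number of genes.
#' @param n_facets number of facets (default 70: 69 reference facets plus
#'   the cell line of interest).
#' @param alpha Dirichlet concentration per gene: a scalar, a vector of
#'   length `n_genes`, or NULL to draw log-uniform in \[0.01, 100\].
#' @param seed integer seed.
#' @return list: `matrix` (genes x facets), `truth` (data.frame gene_id,
#'   alpha, specificity).
#' @export
make_expression <- function(n_genes = 200, n_facets = 70, alpha = NULL,
                            seed = 1) {
  set.seed(.sub_seed(seed, 3))
  if (is.null(alpha)) alpha <- 10^stats::runif(n_genes, -2, 2)
  alpha <- rep_len(alpha, n_genes)
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be > 0")
  mat <- t(vapply(seq_len(n_genes), function(g) {
    w <- stats::rgamma(n_facets, shape = alpha[g])
    if (sum(w) == 0) w[sample(n_facets, 1)] <- 1  # guard tiny-alpha underflow
    total <- stats::rlnorm(1, meanlog = log(100), sdlog = 1)
    w / sum(w) * total
  }, numeric(n_facets)))
  rownames(mat) <- paste0("gene_", seq_len(n_genes))
  colnames(mat) <- c(paste0("facet_", seq_len(n_facets - 1)), "cell_line")
  truth <- data.frame(gene_id = rownames(mat), alpha = alpha,
                      specificity = as.numeric(specificity(mat)),
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Synthetic two-condition 4C replicate call tables
#'
#' Fragments form a HindIII-like grid of exponential lengths spanning
#' `cis_span` around the bait (plus optional trans fragments). Control
#' significance is Bernoulli in a decreasing logistic of bait distance;
#' the experiment flips each fragment's status with a change probability
#' rising logistically with distance, so changed loops are planted to be
#' farther than unchanged ones. p-values are drawn below `alpha` for
#' significant fragments and above otherwise; RPM declines lognormally with
#' distance. Replicate 1 reports every condition-significant fragment;
#' replicate 2 reports each with probability `rep2_prob` (pooling unions
#' replicates, so the condition-level truth is recovered exactly).
#'
#' @param genome genome table (bait placed mid-chromosome 1; trans
#'   fragments on chromosome 2 when present).
#' @param n_fragments number of cis fragments.
#' @param cis_span total cis span covered by fragments, bp.
#' @param mean_frag_len mean fragment length, bp.
#' @param sig_range control significance probabilities at distance 0 and at
#'   the maximum distance (decreasing logistic through these).
#' @param change_range status-flip probabilities at distance 0 and maximum
#'   distance (increasing logistic through these).
#' @param n_trans trans fragments (excluded from distance analyses).
#' @param alpha significance cut-off used when drawing p-values.
#' @param rep2_prob probability that replicate 2 also reports a
#'   condition-significant fragment.
#' @param seed integer seed.
#' @return list: `control_reps`, `experiment_reps` (two call tables each),
#'   `bait` (chrom/start/end list), `truth` (fragment, distance_bp, status
#'   among unchanged/lost/gained/absent).
#' @export
make_fourc_pair <- function(genome, n_fragments = 300, cis_span = 6e6,
                            mean_frag_len = NULL,
                            sig_range = c(0.9, 0.35),
                            change_range = c(0.08, 0.65),
                            n_trans = 10, alpha = 0.05, rep2_prob = 0.7,
                            seed = 1) {
  set.seed(.sub_seed(seed, 4))
  chrom <- genome$chrom[1]
  L <- genome$length[1]
  if (cis_span > L) stop("cis_span exceeds the chromosome")
  if (is.null(mean_frag_len)) mean_frag_len <- cis_span / n_fragments
  len <- pmax(500, round(stats::rexp(n_fragments, 1 / mean_frag_len)))
  len <- round(len / sum(len) * cis_span)  # normalize to the span
  len <- pmax(500, len)
  left0 <- max(0, floor(L / 2 - sum(len) / 2))
  ends <- left0 + cumsum(len)
  starts <- c(left0, ends[-n_fragments])
  bait_i <- which.min(abs((starts + ends) / 2 - L / 2))
  bait <- list(chrom = chrom, start = starts[bait_i], end = ends[bait_i])
  bait_mid <- (bait$start + bait$end) / 2
  mid <- (starts + ends) / 2
  d <- abs(mid - bait_mid)
  dmax <- max(d)
  logit <- function(p) log(p / (1 - p))
  # logistic through the two endpoint probabilities (constant if equal)
  lin_logistic <- function(range) {
    if (range[1] == range[2]) return(rep(range[1], length(d)))
    stats::plogis(logit(range[1]) +
                    (logit(range[2]) - logit(range[1])) * d / dmax)
  }
  sig_prob <- lin_logistic(sig_range)
  change_prob <- lin_logistic(change_range)
  ctrl_sig <- stats::rbinom(n_fragments, 1, sig_prob) == 1
  flip <- stats::rbinom(n_fragments, 1, change_prob) == 1
  exp_sig <- xor(ctrl_sig, flip)
  # trans fragments: rarely significant, never enter distance summaries
  tchrom <- if (nrow(genome) >= 2) genome$chrom[2] else chrom
  tL <- if (nrow(genome) >= 2) genome$length[2] else L
  tstart <- sort(floor(stats::runif(n_trans) * (tL - 5000)))
  tend <- tstart + 4000
  t_ctrl <- stats::rbinom(n_trans, 1, 0.3) == 1
  t_exp <- stats::rbinom(n_trans, 1, 0.3) == 1
  all_chrom <- c(rep(chrom, n_fragments), rep(tchrom, n_trans))
  all_start <- c(starts, tstart); all_end <- c(ends, tend)
  all_d <- c(d, rep(NA_real_, n_trans))
  c_sig <- c(ctrl_sig, t_ctrl); e_sig <- c(exp_sig, t_exp)
  rpm_base <- stats::rlnorm(length(all_chrom), meanlog = log(50), sdlog = 0.5) *
    exp(-ifelse(is.na(all_d), dmax / 2, all_d) / dmax)
  make_rep <- function(sig, full) {
    rep_sig <- sig & (full | stats::runif(length(sig)) < rep2_prob)
    p <- ifelse(rep_sig, stats::runif(length(sig)) * alpha * 0.99,
                alpha + stats::runif(length(sig)) * (1 - alpha) * 0.999)
    fourc_calls(all_chrom, all_start, all_end,
                rpm = round(rpm_base * ifelse(rep_sig, 1, 0.2), 3),
                p_value = p)
  }
  status <- ifelse(c_sig & e_sig, "unchanged",
                   ifelse(c_sig & !e_sig, "lost",
                          ifelse(!c_sig & e_sig, "gained", "absent")))
  truth <- data.frame(fragment = paste0(all_chrom, ":", all_start, "-", all_end),
                      distance_bp = all_d, status = status,
                      stringsAsFactors = FALSE)
  list(control_reps = list(make_rep(c_sig, TRUE), make_rep(c_sig, FALSE)),
       experiment_reps = list(make_rep(e_sig, TRUE), make_rep(e_sig, FALSE)),
       bait = bait, truth = truth)
}

#' Toy genome with planted proximal / distal / internal gene-MRR layouts
#'
#' Builds, per instance, one MRR-gene pair in each category plus background
#' genes, blacklist and H3K9me3 regions (with genes overlapping them, which
#' the control-gene filter must reject) and extra anchor-overlapping genes
#' eligible for control sampling.
#'
#' @param n_each planted instances per category.
#' @param n_background extra loop-connected background genes.
#' @param seed integer seed.
#' @return list: `genome`, `genes` (gene table), `mrrs` (`GRanges`),
#'   `interactions`, `blacklist`, `h3k9me3` (`GRanges`), `truth`
#'   (data.frame gene_id, mrr_id, category).
#' @export
make_gene_loop_toy <- function(n_each = 1, n_background = 60, seed = 1) {
  set.seed(.sub_seed(seed, 5))
  block <- 2e6
  n_blocks <- 3 * n_each + n_background + 10
  L <- block * (n_blocks + 1)
  genome <- genome_table("chr1", L)
  gid <- 0; mrr_list <- list(); gene_rows <- list(); loops <- list()
  truth <- list()
  blk <- 0
  add_gene <- function(tss, name) {
    data.frame(gene_id = name, chrom = "chr1", start0 = tss - 1000,
               end0 = tss + 20000, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_each)) {
    # proximal: gene TSS inside the MRR, no loop elsewhere
    blk <- blk + 1; x <- blk * block
    mrr_list[[length(mrr_list) + 1]] <- c(x, x + 10000)
    gid <- gid + 1
    gene_rows[[gid]] <- add_gene(x + 5000, paste0("prox_", i))
    truth[[length(truth) + 1]] <- c(paste0("prox_", i),
                                    length(mrr_list), "proximal")
    # distal: MRR loops over 500 kb to the promoter
    blk <- blk + 1; x <- blk * block
    mrr_list[[length(mrr_list) + 1]] <- c(x, x + 10000)
    gid <- gid + 1
    tss <- x + 500000
    gene_rows[[gid]] <- add_gene(tss, paste0("dist_", i))
    loops[[length(loops) + 1]] <- c(x + 2000, x + 4000, tss - 1000, tss + 1000)
    truth[[length(truth) + 1]] <- c(paste0("dist_", i),
                                    length(mrr_list), "distal")
    # internal: promoter inside a broad MRR that also loops to it
    blk <- blk + 1; x <- blk * block
    mrr_list[[length(mrr_list) + 1]] <- c(x, x + 50000)
    gid <- gid + 1
    tss <- x + 10000
    gene_rows[[gid]] <- add_gene(tss, paste0("int_", i))
    loops[[length(loops) + 1]] <- c(x + 5000, x + 15000, x + 40000, x + 45000)
    truth[[length(truth) + 1]] <- c(paste0("int_", i),
                                    length(mrr_list), "internal")
  }
  # background genes connected by loops (eligible controls)
  for (b in seq_len(n_background)) {
    blk <- blk + 1; x <- blk * block
    gid <- gid + 1
    gene_rows[[gid]] <- add_gene(x + 5000, paste0("bg_", b))
    loops[[length(loops) + 1]] <- c(x + 4000, x + 6000, x + 300000, x + 302000)
  }
  # genes inside blacklist / H3K9me3 (must never be sampled as controls)
  blk <- blk + 1; xb <- blk * block
  blacklist <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(xb + 1, xb + 50000))
  gid <- gid + 1
  gene_rows[[gid]] <- add_gene(xb + 10000, "blk_gene")
  loops[[length(loops) + 1]] <- c(xb + 9000, xb + 11000, xb + 600000, xb + 602000)
  blk <- blk + 1; xk <- blk * block
  h3k9me3 <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(xk + 1, xk + 50000))
  gid <- gid + 1
  gene_rows[[gid]] <- add_gene(xk + 10000, "k9_gene")
  loops[[length(loops) + 1]] <- c(xk + 9000, xk + 11000, xk + 600000, xk + 602000)
  gene_df <- do.call(rbind, gene_rows)
  genes <- gene_models(gene_df$gene_id, gene_df$chrom, gene_df$start0,
                       gene_df$end0)
  mrrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    vapply(mrr_list, `[`, numeric(1), 1) + 1,
    vapply(mrr_list, `[`, numeric(1), 2)))
  lm <- do.call(rbind, loops)
  interactions <- interaction_set(rep("chr1", nrow(lm)), lm[, 1], lm[, 2],
                                  rep("chr1", nrow(lm)), lm[, 3], lm[, 4])
  truth_df <- as.data.frame(do.call(rbind, truth), stringsAsFactors = FALSE)
  names(truth_df) <- c("gene_id", "mrr_id", "category")
  truth_df$mrr_id <- as.integer(truth_df$mrr_id)
  list(genome = genome, genes = genes, mrrs = mrrs,
       interactions = interactions, blacklist = blacklist,
       h3k9me3 = h3k9me3, truth = truth_df)
}

#' Generate and write every input for an end-to-end run
#'
#' Runs all generators with their default study conditions and writes
#' plain-text inputs (BED, bedGraph, BEDPE-like TSV, expression TSV, 4C
#' call TSVs, chrom.sizes) plus a parameter manifest under `dir`.
#' Byte-identical outputs are produced for identical (parameters, seed).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed fanned out to all generators.
#' @return (invisibly) a list with all in-memory objects and truths.
#' @export
simulate_full <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(2, c(1e7, 5e6), seed)
  write.table(genome, file.path(dir, "genome.chrom.sizes"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  pk <- make_peaks_and_signal(genome, seed = seed)
  write_intervals(pk$peaks, file.path(dir, "h3k27me3_peaks.bed"))
  write_signal(pk$treatment, file.path(dir, "h3k27me3_treatment.bedGraph"))
  write_signal(pk$control, file.path(dir, "h3k27me3_control.bedGraph"))
  write_intervals(pk$truth$mrr, file.path(dir, "truth_mrr.bed"))
  ia <- make_interactions(
    genome,
    state_probs = c(A = 0.3, R = 0.3, B = 0.1, Q = 0.3),
    pair_preference = c(AA = 0.16, AB = 0.04, AQ = 0.08, AR = 0.04,
                        BB = 0.04, BQ = 0.03, BR = 0.04,
                        QQ = 0.16, QR = 0.08, RR = 0.33),
    n_interactions = 20000, seed = seed)
  write_interactions(ia$interactions, file.path(dir, "loops.bedpe"))
  write_intervals(ia$k27ac_peaks, file.path(dir, "k27ac_anchors.bed"))
  write_intervals(ia$k27me3_peaks, file.path(dir, "k27me3_anchors.bed"))
  ex <- make_expression(seed = seed)
  write.table(data.frame(gene_id = rownames(ex$matrix), ex$matrix,
                         check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fc <- make_fourc_pair(genome, seed = seed)
  for (i in 1:2) {
    write.table(fc$control_reps[[i]][, 1:5],
                file.path(dir, paste0("fourc_control_rep", i, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fc$experiment_reps[[i]][, 1:5],
                file.path(dir, paste0("fourc_experiment_rep", i, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(chrom = fc$bait$chrom, start = fc$bait$start,
                         end = fc$bait$end),
              file.path(dir, "fourc_bait.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  toy <- make_gene_loop_toy(seed = seed)
  write.table(toy$genes[, c("gene_id", "chrom", "start", "end", "strand")],
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_intervals(toy$mrrs, file.path(dir, "toy_mrrs.bed"))
  write_interactions(toy$interactions, file.path(dir, "toy_loops.bedpe"))
  write_intervals(toy$blacklist, file.path(dir, "blacklist.bed"))
  write_intervals(toy$h3k9me3, file.path(dir, "h3k9me3.bed"))
  manifest <- data.frame(
    key = c("seed", "genome", "n_clusters", "peaks_per_cluster",
            "n_isolated", "signal_fold", "n_interactions", "n_genes",
            "n_facets", "n_fragments"),
    value = c(seed, paste(genome$chrom, genome$length, collapse = ";"),
              pk$truth$params$n_clusters, pk$truth$params$peaks_per_cluster,
              pk$truth$params$n_isolated, pk$truth$params$signal_fold,
              nrow(ia$interactions), nrow(ex$truth), ncol(ex$matrix),
              nrow(fc$truth)),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genome = genome, peaks = pk, interactions = ia,
                 expression = ex, fourc = fc, gene_toy = toy))
}
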