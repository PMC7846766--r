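# End-to-end driver: consumes the file bundle written by simulate_full()
# (or equivalently formatted real data) and runs every analysis stage,
# writing plain-text result tables.

#' Run the full super-silencer analysis over an input bundle
#'
#' Stages: MRR calling (stitch/score/rank/slope-1 cutoff), anchor state
#' labelling and observed/expected pair enrichment, gene-MRR looping
#' classification with the filtered control gene set, the same-chromosome
#' permutation overlap test of the called MRRs against the planted region
#' list, expression specificity with quartile binning, and differential 4C
#' classification with bait-distance summaries.
#'
#' @param input_dir directory holding the input bundle (see
#'   [simulate_full()] for the file inventory).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the randomized stages (shuffling, control
#'   gene sampling).
#' @param n_shuffles shuffles for the permutation overlap test.
#' @return (invisibly) a named list of the in-memory stage results.
#' @export
run_full_pipeline <- function(input_dir, out_dir, seed = 1,
                              n_shuffles = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(input_dir, ...)
  o <- function(...) file.path(out_dir, ...)
  tsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  genome <- read_chrom_sizes(p("genome.chrom.sizes"))

  # --- MRR calling ---------------------------------------------------------
  peaks <- read_intervals(p("h3k27me3_peaks.bed"), genome)
  treatment <- read_signal(p("h3k27me3_treatment.bedGraph"), genome)
  control <- read_signal(p("h3k27me3_control.bedGraph"), genome)
  called <- call_regions(peaks, treatment, control, mark = "H3K27me3")
  mc <- S4Vectors::mcols(called)
  mrr_tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(called)),
                        start = GenomicRanges::start(called) - 1,
                        end = GenomicRanges::end(called),
                        label = mc$label, score = mc$score, rank = mc$rank,
                        n_constituents = mc$n_constituents)
  tsv(mrr_tab[order(mrr_tab$rank), ], o("mrr_regions.tsv"))
  curve <- attr(called, "curve")
  tsv(data.frame(rank = seq_along(curve$y), score = curve$y,
                 x_scaled = curve$x, y_scaled = curve$y_scaled),
      o("ranked_curve.tsv"))

  # --- anchor states and pair enrichment -----------------------------------
  loops <- read_interactions(p("loops.bedpe"), genome, dedup = FALSE)
  ac <- read_intervals(p("k27ac_anchors.bed"), genome)
  me3 <- read_intervals(p("k27me3_anchors.bed"), genome)
  s1 <- assign_anchor_state(anchor_granges(loops, 1), ac, me3)
  s2 <- assign_anchor_state(anchor_granges(loops, 2), ac, me3)
  enr <- pair_enrichment(s1, s2)
  tsv(enr, o("pair_enrichment.tsv"))

  # --- gene-MRR looping and control genes ----------------------------------
  gtab <- read.table(p("genes.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  genes <- gene_models(gtab$gene_id, gtab$chrom, gtab$start, gtab$end,
                       gtab$strand)
  toy_mrrs <- read_intervals(p("toy_mrrs.bed"))
  toy_loops <- read_interactions(p("toy_loops.bedpe"))
  assoc <- classify_gene_mrr(genes, toy_mrrs, toy_loops)
  tsv(assoc, o("gene_mrr_associations.tsv"))
  n_cat <- table(factor(assoc$category,
                        levels = c("proximal", "distal", "internal")))
  ctrl_genes <- build_control_genes(genes,
                                    read_intervals(p("blacklist.bed")),
                                    read_intervals(p("h3k9me3.bed")),
                                    toy_loops, as.integer(n_cat),
                                    seed = seed)
  writeLines(ctrl_genes, o("control_genes.txt"))

  # --- permutation overlap of called MRRs against the planted list ---------
  truth_mrr <- read_intervals(p("truth_mrr.bed"), genome)
  rich <- called[mc$label == "rich"]
  shuf <- permutation_overlap_test(truth_mrr, rich, genome,
                                   n_shuffles = n_shuffles, seed = seed)
  tsv(data.frame(actual_pct = shuf$actual_pct,
                 mean_expected_pct = mean(shuf$expected_pcts),
                 sd_expected_pct = stats::sd(shuf$expected_pcts),
                 t_test_p = shuf$p_value, empirical_p = shuf$empirical_p,
                 n_shuffles = shuf$n_shuffles),
      o("shuffle_report.tsv"))

  # --- expression specificity ----------------------------------------------
  em <- read.table(p("expression.tsv"), header = TRUE, sep = "\t",
                   row.names = 1, check.names = FALSE)
  spec <- specificity(as.matrix(em))
  spec_tab <- data.frame(gene_id = rownames(em),
                         specificity = as.numeric(spec),
                         entropy_bits = as.numeric(attr(spec, "entropy_bits")),
                         bin = specificity_bins(as.numeric(spec)))
  tsv(spec_tab, o("specificity.tsv"))

  # --- differential 4C ------------------------------------------------------
  ctl <- pool_replicates(list(read_fourc_calls(p("fourc_control_rep1.tsv")),
                              read_fourc_calls(p("fourc_control_rep2.tsv"))))
  expd <- pool_replicates(list(read_fourc_calls(p("fourc_experiment_rep1.tsv")),
                               read_fourc_calls(p("fourc_experiment_rep2.tsv"))))
  bait <- read.table(p("fourc_bait.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  cmp <- bait_distance(compare_conditions(ctl, expd),
                       bait$chrom[1], bait$start[1], bait$end[1])
  tsv(cmp, o("fourc_comparison.tsv"))
  tsv(proportion_unchanged(cmp), o("fourc_proportion_unchanged.tsv"))
  ds <- distance_summary(cmp)
  tsv(ds$summary, o("fourc_distance_summary.tsv"))

  invisible(list(genome = genome, called = called, enrichment = enr,
                 associations = assoc, control_genes = ctrl_genes,
                 shuffle = shuf, specificity = spec_tab, fourc = cmp,
                 distance = ds))
}
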