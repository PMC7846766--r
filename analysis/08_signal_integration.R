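#!/usr/bin/env Rscript
# Integrate the 4C comparison with ChIP-seq signal: total signal areas
# (sum of bin mean x bin size) per 4C region and condition, control-
# condition signal tertiles, and paired per-status tests; plus a TF-peak
# Z-score matrix over the loop-connected regions.

suppressMessages(library(silencerscape))

dir <- "results/simulated_inputs"
cmp <- read.table("results/fourc_comparison.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
# simulated condition tracks: reuse the simulated H3K27me3 coverage as the
# control condition and a flat background as the post-perturbation state
k27me3_ctl <- read_signal(file.path(dir, "h3k27me3_treatment.bedGraph"))
flat <- signal_track("chr1", 0, 1e7, 1)
res <- integrate_fourc_chip(cmp[cmp$chrom == "chr1", ],
                            k27me3_control = k27me3_ctl,
                            k27me3_experiment = flat,
                            k27ac_control = flat, k27ac_experiment = flat,
                            bin_size = 50)
write.table(res$records, "results/fourc_chip_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$paired_tests, "results/fourc_chip_paired_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("4C regions integrated:", nrow(res$records), "\n")
cat("Control-condition H3K27me3 tertiles:\n")
print(table(res$records$k27me3_tertile))
cat("Paired control-vs-experiment tests per status:\n")
print(res$paired_tests, row.names = FALSE, digits = 3)

# TF-binding Z scores over the anchors of the simulated loop list
genome <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
loops <- read_interactions(file.path(dir, "loops.bedpe"), genome,
                           dedup = FALSE)
regions <- unique(c(anchor_granges(loops, 1), anchor_granges(loops, 2)))
set.seed(1)
fake_tf <- function(n) {
  s <- floor(runif(n) * (1e7 - 500))
  GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1, s + 400))
}
tf <- list(tf_a = fake_tf(3000), tf_b = fake_tf(500), tf_c = fake_tf(100))
z <- tf_zscore_matrix(regions[seq_len(min(2000, length(regions)))], tf)
write.table(round(z, 4), "results/tf_zscores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("TF Z-score matrix:", nrow(z), "regions x", ncol(z),
    "factors; column means ~0, sd ~1\n")
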