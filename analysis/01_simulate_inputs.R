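#!/usr/bin/env Rscript
# Generate the synthetic study inputs with planted ground truth: ChIP-seq
# peaks and coverage with 20 planted H3K27me3-rich clusters, a 20,000-loop
# state-labelled interaction list, a 70-facet expression matrix, a
# two-condition 4C replicate pair, and a toy gene/MRR/loop layout.

suppressMessages(library(silencerscape))

seed <- 1
dir <- "results/simulated_inputs"
res <- simulate_full(dir, seed = seed)

cat("Simulated input bundle written to", dir, "\n")
cat(" - planted MRR clusters:", length(res$peaks$truth$mrr), "\n")
cat(" - H3K27me3 peaks:", length(res$peaks$peaks), "\n")
cat(" - Hi-C style loops:", nrow(res$interactions$interactions), "\n")
cat(" - expression genes x facets:", nrow(res$expression$matrix), "x",
    ncol(res$expression$matrix), "\n")
cat(" - 4C fragments (incl. trans):", nrow(res$fourc$truth), "\n")
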