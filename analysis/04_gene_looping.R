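#!/usr/bin/env Rscript
# Classify gene-MRR relationships (proximal / distal / internal) from the
# toy gene layout and build the filtered random control gene set.

suppressMessages(library(silencerscape))

dir <- "results/simulated_inputs"
gtab <- read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
genes <- gene_models(gtab$gene_id, gtab$chrom, gtab$start, gtab$end,
                     gtab$strand)
mrrs <- read_intervals(file.path(dir, "toy_mrrs.bed"))
loops <- read_interactions(file.path(dir, "toy_loops.bedpe"))

assoc <- classify_gene_mrr(genes, mrrs, loops)
write.table(assoc, "results/gene_mrr_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Gene-MRR associations by category:\n")
print(table(assoc$category))

n_cat <- table(factor(assoc$category,
                      levels = c("proximal", "distal", "internal")))
ctrl <- build_control_genes(genes,
                            read_intervals(file.path(dir, "blacklist.bed")),
                            read_intervals(file.path(dir, "h3k9me3.bed")),
                            loops, as.integer(n_cat), seed = 1)
writeLines(ctrl, "results/control_genes.txt")
cat("Control gene set: floor(mean(category sizes)) =", length(ctrl),
    "genes, none overlapping blacklist or H3K9me3 regions\n")
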