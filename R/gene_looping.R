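# Classification of gene-MRR relationships (proximal / distal / internal)
# via chromatin-interaction anchors, and the filtered random control gene
# set used for expression comparisons.

#' Build a gene model table
#'
#' @param gene_id character IDs (unique).
#' @param chrom chromosome names.
#' @param start0,end0 gene body, BED 0-based half-open.
#' @param strand "+" or "-" (TSS is the 5' end of the body).
#' @param promoter_halfwidth symmetric promoter window around the TSS, bp.
#' @return data.frame with body and promoter coordinates (0-based) and tss.
#' @export
gene_models <- function(gene_id, chrom, start0, end0, strand = "+",
                        promoter_halfwidth = 2000) {
  if (anyDuplicated(gene_id)) stop("duplicated gene_id")
  if (any(start0 >= end0)) stop("invalid gene body interval(s)")
  strand <- rep_len(strand, length(gene_id))
  tss <- ifelse(strand == "+", start0, end0 - 1)
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = as.numeric(start0), end = as.numeric(end0),
             strand = strand, tss = as.numeric(tss),
             prom_start = pmax(0, tss - promoter_halfwidth),
             prom_end = tss + promoter_halfwidth,
             stringsAsFactors = FALSE)
}

.gene_body_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1, genes$end))
}

.gene_prom_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$prom_start + 1, genes$prom_end))
}

#' Classify gene-MRR looping as proximal, distal or internal
#'
#' For each (gene, MRR) pair:
#' * proximal evidence: the promoter overlaps the MRR, or the promoter and
#'   the MRR share an interaction anchor;
#' * loop evidence: some interaction has one anchor overlapping the MRR and
#'   the other overlapping the promoter;
#' * internal: proximal evidence plus a supporting loop whose two anchors
#'   both fall in the same MRR;
#' * distal: loop evidence where the promoter-side anchor does not overlap
#'   the MRR.
#' Precedence: internal > proximal > distal; one category per pair.
#'
#' @param genes gene table from [gene_models()].
#' @param mrrs `GRanges` of MRRs.
#' @param interactions `interaction_set`.
#' @return data.frame: gene_id, mrr_id (index into `mrrs`), category,
#'   evidence flags (`prom_overlap`, `shared_anchor`, `loop`,
#'   `internal_loop`) and supporting interaction IDs (comma-separated row
#'   indices).
#' @export
classify_gene_mrr <- function(genes, mrrs, interactions) {
  prom <- .gene_prom_gr(genes)
  a1 <- anchor_granges(interactions, 1)
  a2 <- anchor_granges(interactions, 2)
  res <- list()
  for (m in seq_along(mrrs)) {
    mrr <- mrrs[m]
    # anchors overlapping this MRR / sides
    m1 <- overlaps_any(a1, mrr); m2 <- overlaps_any(a2, mrr)
    for (g in seq_len(nrow(genes))) {
      pg <- prom[g]
      prom_overlap <- overlaps_any(pg, mrr)
      p1 <- overlaps_any(a1, pg); p2 <- overlaps_any(a2, pg)
      # promoter and MRR co-occupy one anchor
      shared_anchor <- any((p1 & m1) | (p2 & m2))
      # one anchor on the MRR, the other on the promoter
      loop_ix <- which((m1 & p2) | (m2 & p1))
      loop <- length(loop_ix) > 0
      # both anchors of a supporting loop inside this MRR
      internal_ix <- loop_ix[m1[loop_ix] & m2[loop_ix]]
      proximal_ev <- prom_overlap || shared_anchor
      internal_ev <- proximal_ev && length(internal_ix) > 0
      # distal: the promoter-side anchor itself clear of the MRR
      distal_ix <- loop_ix[(m1[loop_ix] & p2[loop_ix] & !m2[loop_ix]) |
                             (m2[loop_ix] & p1[loop_ix] & !m1[loop_ix])]
      distal_ev <- length(distal_ix) > 0
      category <- if (internal_ev) "internal"
                  else if (proximal_ev) "proximal"
                  else if (distal_ev) "distal"
                  else NA_character_
      if (is.na(category)) next
      support <- if (internal_ev) internal_ix
                 else if (proximal_ev) loop_ix
                 else distal_ix
      res[[length(res) + 1]] <- data.frame(
        gene_id = genes$gene_id[g], mrr_id = m, category = category,
        prom_overlap = prom_overlap, shared_anchor = shared_anchor,
        loop = loop, internal_loop = length(internal_ix) > 0,
        support = paste(support, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(gene_id = character(), mrr_id = integer(),
                      category = character(), prom_overlap = logical(),
                      shared_anchor = logical(), loop = logical(),
                      internal_loop = logical(), support = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Build the filtered random control gene set
#'
#' Filters out genes whose body overlaps ENCODE-blacklist-style regions or
#' H3K9me3 peaks (constitutive heterochromatin), retains genes whose body or
#' promoter overlaps any interaction anchor, then samples
#' `floor(mean(n_per_category))` genes uniformly without replacement.
#'
#' @param genes gene table from [gene_models()].
#' @param blacklist,h3k9me3 `GRanges` exclusion sets (may be empty).
#' @param interactions `interaction_set`.
#' @param n_per_category integer vector of gene counts in the
#'   proximal/distal/internal categories.
#' @param seed integer seed (required: sampling must be reproducible).
#' @param anchors_only restrict the interaction-overlap filter to promoters.
#' @return character vector of sampled gene IDs.
#' @export
build_control_genes <- function(genes, blacklist, h3k9me3, interactions,
                                n_per_category, seed,
                                anchors_only = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  body <- .gene_body_gr(genes)
  prom <- .gene_prom_gr(genes)
  excl <- overlaps_any(body, blacklist) | overlaps_any(body, h3k9me3)
  anchors <- c(anchor_granges(interactions, 1),
               anchor_granges(interactions, 2))
  hit <- if (anchors_only) overlaps_any(prom, anchors)
         else overlaps_any(body, anchors) | overlaps_any(prom, anchors)
  eligible <- genes$gene_id[!excl & hit]
  n_sample <- floor(mean(n_per_category))
  if (length(eligible) < n_sample)
    stop("only ", length(eligible), " eligible control genes for a sample of ",
         n_sample)
  set.seed(seed)
  sample(eligible, n_sample, replace = FALSE)
}
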