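# Facet-averaged expression, entropy-based specificity, specificity
# binning, and cross-cell-line peak-state assignment for state-change
# fold-change comparisons.

#' Average an expression matrix over sample facets
#'
#' Each facet (e.g. a FANTOM5 tissue/cell-type grouping) receives the
#' arithmetic mean of its samples; a cell line of interest enters as its own
#' facet, e.g. 69 reference facets + 1 cell line = 70 facets.
#'
#' @param sample_matrix numeric matrix genes x samples (colnames = samples).
#' @param facet_map named character vector mapping each sample to a facet.
#' @return numeric matrix genes x facets.
#' @export
facet_average <- function(sample_matrix, facet_map) {
  samples <- colnames(sample_matrix)
  if (is.null(samples) || !all(samples %in% names(facet_map)))
    stop("every sample column must be mapped to a facet")
  facets <- unique(facet_map[samples])
  out <- sapply(facets, function(f) {
    cols <- samples[facet_map[samples] == f]
    if (length(cols) == 0) stop("facet with zero samples: ", f)
    rowMeans(sample_matrix[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(
    rownames(sample_matrix), facets))
  colnames(out) <- facets
  out
}

#' Entropy-based expression specificity
#'
#' For a nonnegative expression vector x over N facets,
#' specificity = 1 - entropy(x) / log2(N), with p_i = x_i / sum(x), entropy
#' in bits and the 0*log(0) = 0 convention. A uniform profile scores 0, a
#' point mass 1; an all-zero vector is undefined (NA).
#'
#' @param x numeric vector (one gene) or matrix genes x facets.
#' @return numeric vector of specificities in \[0, 1\] (NA where the row sum
#'   is 0), with attribute `entropy_bits`.
#' @export
specificity <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(x < 0, na.rm = TRUE)) stop("negative expression value")
  N <- ncol(x)
  if (N < 2) stop("need >= 2 facets")
  tot <- rowSums(x)
  p <- x / tot
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ent <- -rowSums(plogp)
  # clamp away sub-ulp excursions so the [0, 1] bounds hold exactly
  spec <- ifelse(tot > 0, pmin(1, pmax(0, 1 - ent / log2(N))), NA_real_)
  attr(spec, "entropy_bits") <- ifelse(tot > 0, ent, NA_real_)
  spec
}

#' Bin specificity scores by quartiles
#'
#' Q1 and Q3 of the defined scores are the cut-offs: a score is "low" iff it
#' is <= Q1 and < Q3, "high" iff >= Q3 and > Q1, otherwise "mid"; undefined
#' (NA) scores stay "undefined". When Q1 == Q3 (degenerate spread) all
#' defined scores are "mid". Quantiles use linear interpolation.
#'
#' @param scores numeric specificity scores (NAs allowed).
#' @return character vector in {"low", "mid", "high", "undefined"}.
#' @export
specificity_bins <- function(scores) {
  def <- scores[!is.na(scores)]
  if (length(def) < 4) stop("need >= 4 defined scores for quartile binning")
  q <- stats::quantile(def, c(0.25, 0.75), type = 7, names = FALSE)
  ifelse(is.na(scores), "undefined",
         ifelse(scores <= q[1] & scores < q[2], "low",
                ifelse(scores >= q[2] & scores > q[1], "high", "mid")))
}

#' Assign a chromatin state to each gene in one cell line
#'
#' The union of gene body and promoter is tested for overlap against the
#' cell line's super-enhancers, MRRs, typical H3K27ac and typical H3K27me3
#' peak sets, with precedence SE > MRR > H3K27ac > H3K27me3; genes
#' overlapping none are "Others".
#'
#' @param genes gene table from [gene_models()].
#' @param se,mrr,k27ac,k27me3 `GRanges` region sets (may be empty).
#' @return character vector of states along `genes`.
#' @export
assign_gene_state <- function(genes, se, mrr, k27ac, k27me3) {
  body <- .gene_body_gr(genes)
  prom <- .gene_prom_gr(genes)
  hit <- function(set) overlaps_any(body, set) | overlaps_any(prom, set)
  ifelse(hit(se), "SE",
         ifelse(hit(mrr), "MRR",
                ifelse(hit(k27ac), "H3K27ac",
                       ifelse(hit(k27me3), "H3K27me3", "Others"))))
}

#' Per-gene state-change categories and expression fold changes
#'
#' Categories are "stateA vs stateB" strings; fold change is
#' log2((expr_B + pseudocount) / (expr_A + pseudocount)).
#'
#' @param labels_a,labels_b named character vectors of gene states in the
#'   two cell lines (shared gene universe).
#' @param expr_a,expr_b named numeric expression vectors on the same genes.
#' @param pseudocount added to both expressions before the ratio (default 1
#'   on the expression unit).
#' @return data.frame: gene_id, state_a, state_b, category, log2fc.
#' @export
state_change_table <- function(labels_a, labels_b, expr_a, expr_b,
                               pseudocount = 1) {
  genes <- names(labels_a)
  if (is.null(genes) ||
      !setequal(genes, names(labels_b)) ||
      !all(genes %in% names(expr_a)) || !all(genes %in% names(expr_b)))
    stop("gene universes of labels and expression must match")
  data.frame(
    gene_id = genes,
    state_a = unname(labels_a[genes]),
    state_b = unname(labels_b[genes]),
    category = paste(labels_a[genes], "vs", labels_b[genes]),
    log2fc = log2((expr_b[genes] + pseudocount) /
                    (expr_a[genes] + pseudocount)),
    row.names = NULL, stringsAsFactors = FALSE)
}
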