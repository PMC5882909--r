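# Focal-gene co-expression networks from FPKM matrices.
#
# The workflow mirrors the Cytoscape expression-correlation approach used for
# cotton fiber development: log2(FPKM + 1), Pearson correlation of every gene
# with a focal gene across developmental stages, inclusive thresholds
# r >= 0.95 (positively co-expressed, PCoEG) and r <= -0.95 (NCoEG).

#' Validate an FPKM expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames), stages in columns.
#' @return The matrix, invisibly validated.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("genes must be named", call. = FALSE)
  if (any(values < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  values
}

#' Log2 transform with pseudocount
#'
#' @param matrix Non-negative expression matrix.
#' @param pseudocount Added before log2 (default 1, so 0 maps to 0).
#' @return Transformed matrix.
#' @export
log2_transform <- function(matrix, pseudocount = 1.0) {
  matrix <- expression_matrix(matrix)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  log2(matrix + pseudocount)
}

#' Pearson correlation of every gene with a focal gene
#'
#' Genes with zero variance across stages have undefined correlation; they
#' are excluded and reported in the `excluded` attribute.
#'
#' @param matrix Expression matrix (typically log2-transformed), >= 3 stages.
#' @param focal Focal gene id (must have nonzero variance).
#' @return Named numeric vector of r over the other genes, with attribute
#'   `excluded` listing zero-variance genes.
#' @export
focal_correlations <- function(matrix, focal) {
  if (!(focal %in% rownames(matrix))) {
    stop("focal gene ", focal, " not in matrix", call. = FALSE)
  }
  if (ncol(matrix) < 3L) stop("need >= 3 stages", call. = FALSE)
  f <- matrix[focal, ]
  if (stats::sd(f) == 0) stop("focal profile has zero variance", call. = FALSE)
  others <- matrix[setdiff(rownames(matrix), focal), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  excluded <- rownames(others)[sds == 0]
  ok <- others[sds > 0, , drop = FALSE]
  r <- as.vector(cor(t(ok), f))
  names(r) <- rownames(ok)
  attr(r, "excluded") <- excluded
  r
}

#' Threshold correlations into a co-expression network
#'
#' Inclusive thresholds: r >= `pos_thr` joins the positive set, r <=
#' `neg_thr` the negative set; everything else is excluded.
#'
#' @param r_values Named vector from [focal_correlations()].
#' @param pos_thr,neg_thr Thresholds (default 0.95 / -0.95).
#' @param focal Focal gene id (carried on the result).
#' @return An object of class `coexpression_network` with `focal`, `edges`
#'   (data frame gene, r, sign), `pcoeg`, `ncoeg`.
#' @export
build_network <- function(r_values, pos_thr = 0.95, neg_thr = -0.95,
                          focal = attr(r_values, "focal") %||% "focal") {
  if (neg_thr >= pos_thr) stop("neg_thr must be < pos_thr", call. = FALSE)
  pcoeg <- names(r_values)[!is.na(r_values) & r_values >= pos_thr]
  ncoeg <- names(r_values)[!is.na(r_values) & r_values <= neg_thr]
  genes <- c(pcoeg, ncoeg)
  edges <- data.frame(
    gene = genes,
    r = unname(r_values[genes]),
    sign = rep(c("pos", "neg"), c(length(pcoeg), length(ncoeg))),
    stringsAsFactors = FALSE
  )
  structure(
    list(focal = focal, edges = edges, pcoeg = pcoeg, ncoeg = ncoeg),
    class = "coexpression_network"
  )
}

#' Per-stage distribution summary of a gene set
#'
#' Median and quartiles (linear-interpolation percentiles) of expression over
#' a gene set at each stage -- the box-plot summary of cumulative expression
#' across fiber development.
#'
#' @param matrix Expression matrix.
#' @param gene_set Non-empty character vector of gene ids.
#' @return Matrix with rows `p25`, `median`, `p75` and one column per stage.
#' @export
stage_summary <- function(matrix, gene_set) {
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, rownames(matrix))
  if (length(missing)) {
    stop("genes not in matrix: ", paste(head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  sub <- matrix[gene_set, , drop = FALSE]
  apply(sub, 2, function(col) {
    q <- quantile(col, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(p25 = q[1], median = q[2], p75 = q[3])
  })
}
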