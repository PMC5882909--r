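# Bundled reference tables: the published cotton CAMTA gene coordinates and
# the duplicated-pair Ka/Ks values, shipped as plain TSV so the dating and
# duplication-typing arithmetic can be exercised without genome downloads.

#' Published cotton CAMTA gene coordinates
#'
#' Chromosome locations, strands, protein lengths and intron counts of the
#' 22 cotton CAMTA genes (6 GaCAMTA, 7 GrCAMTA, 9 GhCAMTA).
#'
#' @param as_models Return [gene_model()] objects (single-exon placeholders
#'   spanning the gene body) instead of the raw table.
#' @return Data frame, or list of `gene_model`s when `as_models = TRUE`.
#' @export
camta_reference_genes <- function(as_models = FALSE) {
  path <- system.file("extdata", "table1_gene_models.tsv",
                      package = "camtakit", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!as_models) return(df)
  lapply(seq_len(nrow(df)), function(i) {
    gene_model(df$id[i], df$chromosome[i], df$strand[i], df$start[i],
               df$end[i], cbind(df$start[i], df$end[i]))
  })
}

#' Published duplicated-pair Ka/Ks values
#'
#' The six duplicated cotton CAMTA pairs with their reported Ka and Ks,
#' inputs for the ratio/selection/dating arithmetic.
#'
#' @return Data frame with `id_a`, `id_b`, `ka`, `ks` and the printed
#'   ratio/date/selection/type columns.
#' @export
camta_reference_pairs <- function() {
  path <- system.file("extdata", "table2_kaks.tsv",
                      package = "camtakit", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
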