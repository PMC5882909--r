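# Gene models: chromosome, strand, coordinates and exon list (1-based,
# inclusive, GFF3 conventions).

#' Construct a gene model
#'
#' @param id Gene identifier.
#' @param chromosome Chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene bounds, `start <= end`.
#' @param exons Two-column matrix (or data frame) of exon `start`, `end`
#'   pairs within the gene bounds; non-overlapping. Order is normalised.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chromosome, strand, start, end, exons) {
  gm <- structure(
    list(
      id = id, chromosome = chromosome, strand = strand,
      start = as.integer(start), end = as.integer(end),
      exons = matrix(as.integer(as.matrix(exons)), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
    ),
    class = "gene_model"
  )
  validate_gene_model(gm)
}

validate_gene_model <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (!(gm$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for gene ", gm$id, call. = FALSE)
  }
  if (gm$start > gm$end) {
    stop("start > end for gene ", gm$id, call. = FALSE)
  }
  ex <- gm$exons[order(gm$exons[, 1]), , drop = FALSE]
  if (any(ex[, 1] > ex[, 2])) {
    stop("exon start > end in gene ", gm$id, call. = FALSE)
  }
  if (any(ex[, 1] < gm$start) || any(ex[, 2] > gm$end)) {
    stop("exon outside gene bounds in gene ", gm$id, call. = FALSE)
  }
  if (nrow(ex) > 1L && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
    stop("overlapping exons in gene ", gm$id, call. = FALSE)
  }
  gm$exons <- ex
  gm
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand genes.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param model A `gene_model`.
#' @return Spliced sequence (sense strand).
#' @export
splice_cds <- function(genome, model) {
  model <- validate_gene_model(model)
  if (!(model$chromosome %in% names(genome))) {
    stop("chromosome ", model$chromosome, " not in genome", call. = FALSE)
  }
  chrom <- genome[[model$chromosome]]
  parts <- substring(chrom, model$exons[, 1], model$exons[, 2])
  s <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

#' Exon/intron structure signatures and grouping
#'
#' Signature = (intron count, exon-length vector); two genes share a group
#' when intron counts are equal and every exon length agrees within a
#' relative tolerance.
#'
#' @param models List of `gene_model` objects.
#' @param rel_tol Relative exon-length tolerance (default 0.2).
#' @return Data frame with `id`, `n_introns`, `exon_lengths` (list column)
#'   and integer `group`.
#' @export
gene_structure_signature <- function(models, rel_tol = 0.2) {
  if (!length(models)) {
    return(data.frame(id = character(), n_introns = integer(),
                      group = integer()))
  }
  ids <- vapply(models, `[[`, character(1), "id")
  sig <- lapply(models, function(gm) {
    gm <- validate_gene_model(gm)
    as.integer(gm$exons[, 2] - gm$exons[, 1] + 1L)
  })
  n <- length(models)
  compatible <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    all(abs(a - b) <= rel_tol * pmax(a, b))
  }
  group <- seq_len(n)
  root <- function(i) { while (group[i] != i) i <- group[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (compatible(sig[[i]], sig[[j]])) {
          ri <- root(i); rj <- root(j)
          if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), root, integer(1))
  out <- data.frame(
    id = ids,
    n_introns = vapply(sig, function(s) length(s) - 1L, integer(1)),
    group = as.integer(factor(roots)),
    stringsAsFactors = FALSE
  )
  out$exon_lengths <- sig
  out
}
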