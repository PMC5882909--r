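# File I/O: FASTA via Biostrings, GFF3 models (written in-package, read back
# through rtracklayer), expression/truth tables as TSV.

#' Read a FASTA file
#'
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(x)
         else Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' One `gene` feature plus child `exon` features per model; 1-based,
#' inclusive coordinates.
#'
#' @param models List of [gene_model()]s.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    gm <- validate_gene_model(gm)
    lines <- c(lines, sprintf(
      "%s\tcamtakit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      gm$chromosome, gm$start, gm$end, gm$strand, gm$id
    ))
    for (k in seq_len(nrow(gm$exons))) {
      lines <- c(lines, sprintf(
        "%s\tcamtakit\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        gm$chromosome, gm$exons[k, 1], gm$exons[k, 2], gm$strand,
        gm$id, k, gm$id
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses with \pkg{rtracklayer} and assembles `gene` features with their
#' `exon` children into [gene_model()] objects. Genes without exon children
#' become single-exon genes spanning the gene body.
#'
#' @param path GFF3 path.
#' @return List of `gene_model`s.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    parent <- if ("Parent" %in% names(exons) && nrow(exons)) {
      vapply(exons$Parent, function(p) {
        if (length(p)) as.character(p)[1] else NA_character_
      }, character(1))
    } else character(0)
    ex <- exons[!is.na(parent) & parent == g$ID, , drop = FALSE]
    coords <- if (nrow(ex)) {
      cbind(ex$start, ex$end)
    } else {
      cbind(g$start, g$end)
    }
    gene_model(g$ID, as.character(g$seqnames), as.character(g$strand),
               g$start, g$end, coords)
  })
}

#' Read / write an expression matrix TSV
#'
#' Row = gene, column = stage, first column `gene`, header row.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  expression_matrix(m)
}

#' @rdname read_expression
#' @param matrix Expression matrix to write.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-expression network as SIF, GraphML and membership TSV
#'
#' @param network A `coexpression_network`.
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>.graphml` and `<prefix>_members.tsv`.
#' @export
write_network <- function(network, prefix) {
  sif <- sprintf("%s\t%s\t%s", network$focal, network$edges$sign,
                 network$edges$gene)
  writeLines(sif, paste0(prefix, ".sif"))
  write_tsv(network$edges, paste0(prefix, "_members.tsv"))
  nodes <- unique(c(network$focal, network$edges$gene))
  xml <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"r\" for=\"edge\" attr.name=\"r\" attr.type=\"double\"/>",
    "  <graph edgedefault=\"undirected\">",
    sprintf("    <node id=\"%s\"/>", nodes),
    sprintf(paste0("    <edge source=\"%s\" target=\"%s\">",
                   "<data key=\"r\">%.6f</data></edge>"),
            network$focal, network$edges$gene, network$edges$r),
    "  </graph>",
    "</graphml>"
  )
  writeLines(xml, paste0(prefix, ".graphml"))
  invisible(prefix)
}

#' Write motif match coordinates as BED (0-based, half-open)
#'
#' @param matches Data frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional `name`.
#' @param path Output path.
#' @export
write_bed <- function(matches, path) {
  bed <- data.frame(
    chrom = matches$chrom,
    start = matches$start - 1L,
    end = matches$end,
    name = if ("name" %in% names(matches)) matches$name else ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
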