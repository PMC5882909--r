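# Promoter extraction, IUPAC degenerate motif scanning and Fisher's-exact
# enrichment against a random control set.
#
# The default motifs are the CAMTA binding cis-elements MCGCGB ((A/C)CGCG(C/G/T))
# and MCGTGT ((A/C)CGTGT), scanned over 1000-bp upstream promoters.

CAMTA_MOTIFS <- c("MCGCGB", "MCGTGT")

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Expand an IUPAC degenerate motif into a matcher
#'
#' @param motif IUPAC string (ACGT plus ambiguity codes).
#' @return An object of class `iupac_matcher` with the motif, its regex, its
#'   reverse-complement regex, the full expansion set and the motif length.
#' @examples
#' m <- iupac_expand("MCGCGB")
#' "ACGCGT" %in% m$expansion
#' @export
iupac_expand <- function(motif) {
  motif <- toupper(motif)
  chars <- strsplit(motif, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad)) {
    stop("non-IUPAC symbol(s): ", paste(unique(bad), collapse = ","),
         call. = FALSE)
  }
  classes <- IUPAC_CLASSES[chars]
  to_regex <- function(cls) {
    paste(vapply(cls, function(x) {
      if (length(x) == 1L) x else paste0("[", paste(x, collapse = ""), "]")
    }, character(1)), collapse = "")
  }
  expansion <- do.call(paste0, expand.grid(classes, stringsAsFactors = FALSE))
  rc <- revcomp(motif)
  rc_classes <- IUPAC_CLASSES[strsplit(rc, "")[[1]]]
  structure(
    list(
      motif = motif, length = length(chars),
      regex = to_regex(classes), rc_regex = to_regex(rc_classes),
      expansion = sort(expansion)
    ),
    class = "iupac_matcher"
  )
}

as_matchers <- function(motifs) {
  if (inherits(motifs, "iupac_matcher")) return(list(motifs))
  lapply(motifs, function(m) if (inherits(m, "iupac_matcher")) m else iupac_expand(m))
}

# All (overlapping) match start positions of a regex in a sequence.
overlap_starts <- function(regex, seq) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Scan a promoter for degenerate motifs
#'
#' Counts all (possibly overlapping) match positions of each motif, plus
#' matches of each motif's reverse complement when `both_strands` is on.
#' Coordinates hit by more than one motif/strand are deduplicated. `N` bases
#' in the subject never match.
#'
#' @param promoter DNA sequence (string).
#' @param motifs IUPAC strings or `iupac_matcher`s.
#' @param both_strands Also scan reverse-complement motifs (default TRUE).
#' @return List with `count` and `positions` (data frame `start`, `end`).
#' @export
scan_promoter <- function(promoter, motifs = CAMTA_MOTIFS, both_strands = TRUE) {
  promoter <- toupper(promoter)
  matchers <- as_matchers(motifs)
  hits <- lapply(matchers, function(m) {
    starts <- overlap_starts(m$regex, promoter)
    if (both_strands) {
      starts <- c(starts, overlap_starts(m$rc_regex, promoter))
    }
    if (!length(starts)) return(NULL)
    data.frame(start = starts, end = starts + m$length - 1L)
  })
  pos <- do.call(rbind, hits)
  if (is.null(pos) || !nrow(pos)) {
    return(list(count = 0L,
                positions = data.frame(start = integer(), end = integer())))
  }
  pos <- unique(pos[order(pos$start, pos$end), , drop = FALSE])
  rownames(pos) <- NULL
  list(count = nrow(pos), positions = pos)
}

#' Extract upstream promoter sequences
#'
#' Plus-strand gene: the `length` bases ending immediately before the gene
#' start. Minus-strand gene: reverse complement of the `length` bases
#' starting immediately after the gene end. Promoters running off a
#' chromosome edge are truncated and flagged.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param models List of `gene_model`s.
#' @param length Promoter length in bp (default 1000).
#' @return An object of class `promoter_set`: list with `entries` (named
#'   character vector), `promoter_length`, `truncated_flags`.
#' @export
extract_promoters <- function(genome, models, length = 1000L) {
  entries <- character(0)
  trunc <- logical(0)
  for (gm in models) {
    gm <- validate_gene_model(gm)
    if (!(gm$chromosome %in% names(genome))) {
      stop("chromosome ", gm$chromosome, " not in genome", call. = FALSE)
    }
    chrom <- genome[[gm$chromosome]]
    clen <- nchar(chrom)
    if (gm$strand == "+") {
      from <- max(1L, gm$start - length)
      to <- gm$start - 1L
      seq <- if (to >= from) substring(chrom, from, to) else ""
    } else {
      from <- gm$end + 1L
      to <- min(clen, gm$end + length)
      seq <- if (to >= from) revcomp(substring(chrom, from, to)) else ""
    }
    entries[gm$id] <- seq
    trunc[gm$id] <- nchar(seq) < length
  }
  structure(
    list(entries = entries, promoter_length = as.integer(length),
         truncated_flags = trunc),
    class = "promoter_set"
  )
}

promoter_sequences <- function(promoters) {
  if (inherits(promoters, "promoter_set")) promoters$entries else promoters
}

#' Fraction of promoters containing at least one motif match
#'
#' The presence/absence "frequency of occurrence" statistic; a per-promoter
#' mean match count is available via `mode = "count"`.
#'
#' @param promoters A `promoter_set` or named character vector.
#' @param motifs IUPAC strings or matchers.
#' @param both_strands Scan both strands (default TRUE).
#' @param mode `"presence"` (default) or `"count"`.
#' @return List with `n_total`, `n_with`, `frequency`.
#' @export
set_frequency <- function(promoters, motifs = CAMTA_MOTIFS,
                          both_strands = TRUE,
                          mode = c("presence", "count")) {
  mode <- match.arg(mode)
  seqs <- promoter_sequences(promoters)
  if (!length(seqs)) stop("empty promoter set", call. = FALSE)
  counts <- vapply(seqs, function(s) {
    scan_promoter(s, motifs, both_strands)$count
  }, integer(1))
  n_with <- sum(counts > 0L)
  freq <- if (mode == "presence") n_with / length(seqs) else mean(counts)
  list(n_total = length(seqs), n_with = n_with, frequency = freq)
}

#' Two-sided Fisher's exact test for motif enrichment
#'
#' Exact p by summing hypergeometric probabilities no larger than that of
#' the observed table (with the customary relative tolerance); sample odds
#' ratio, with 0.5 added to all cells only when some cell is zero.
#'
#' @param n_with_a,n_total_a Promoters with a match / total, group A.
#' @param n_with_b,n_total_b Same for group B (control).
#' @return List with `odds_ratio`, `p_value` and the input counts.
#' @export
fisher_enrichment <- function(n_with_a, n_total_a, n_with_b, n_total_b) {
  if (n_total_a <= 0 || n_total_b <= 0) stop("zero totals", call. = FALSE)
  if (n_with_a < 0 || n_with_a > n_total_a ||
      n_with_b < 0 || n_with_b > n_total_b) {
    stop("counts out of range", call. = FALSE)
  }
  m <- n_with_a + n_with_b            # total "with" (white balls)
  k <- n_total_a                      # drawn (group A column margin)
  total <- n_total_a + n_total_b
  support <- max(0, k + m - total):min(k, m)
  probs <- dhyper(support, m, total - m, k)
  p_obs <- dhyper(n_with_a, m, total - m, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  a <- n_with_a; b <- n_total_a - n_with_a
  c_ <- n_with_b; d <- n_total_b - n_with_b
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(
    odds_ratio = (a / b) / (c_ / d), p_value = p,
    n_with_a = n_with_a, n_total_a = n_total_a,
    n_with_b = n_with_b, n_total_b = n_total_b
  )
}

#' Motif enrichment of a promoter set against a control
#'
#' @param set_promoters,control_promoters Promoter sets (or named vectors).
#' @param motifs IUPAC motifs (default the CAMTA cis-elements).
#' @param set_name Label for the test set.
#' @param both_strands Scan both strands.
#' @return An object of class `motif_enrichment_result` with per-set counts,
#'   frequencies, odds ratio and two-sided Fisher p-value.
#' @export
motif_enrichment <- function(set_promoters, control_promoters,
                             motifs = CAMTA_MOTIFS, set_name = "set",
                             both_strands = TRUE) {
  fs <- set_frequency(set_promoters, motifs, both_strands)
  fc <- set_frequency(control_promoters, motifs, both_strands)
  ft <- fisher_enrichment(fs$n_with, fs$n_total, fc$n_with, fc$n_total)
  structure(
    list(
      set_name = set_name,
      n_total = fs$n_total, n_with_motif = fs$n_with,
      frequency = fs$frequency,
      control_n_total = fc$n_total, control_n_with = fc$n_with,
      control_frequency = fc$frequency,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    ),
    class = "motif_enrichment_result"
  )
}

#' Sample a random control gene set
#'
#' Uniform, seeded sample without replacement from the genes not in any
#' exclusion set -- the "random promoter set" control design.
#'
#' @param all_genes Character vector of candidate gene ids.
#' @param exclude Character vector (or list of vectors) of ids to exclude.
#' @param n Control size (default 700).
#' @param seed Seed.
#' @return Character vector of `n` gene ids.
#' @export
sample_control <- function(all_genes, exclude = character(), n = 700L, seed = 1L) {
  exclude <- unique(unlist(exclude))
  pool <- setdiff(all_genes, exclude)
  if (length(pool) < n) {
    stop("only ", length(pool), " candidate genes for a control of ", n,
         call. = FALSE)
  }
  if (length(pool) == n) return(pool)
  with_seed(seed, sample(pool, n))
}
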