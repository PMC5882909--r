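# Pairwise alignment, paralog/ortholog detection, NG86 Ka/Ks, selection
# labels, duplication typing and molecular-clock dating.

blosum62 <- function() {
  if (is.null(.camta_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .camta_cache$blosum62 <- e$BLOSUM62
  }
  .camta_cache$blosum62
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (open 10, extend 0.5; a gap of length L costs open + L * extend). Identity
#' is the percent of aligned (both-non-gap) columns that are identical;
#' coverage is the aligned-region length as a percent of the longer input.
#'
#' @param a,b Amino-acid sequences (strings or `protein_record`s).
#' @param gap_open,gap_extend Affine gap costs.
#' @return An object of class `pairwise_alignment` with `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `score`, `identity_pct`, `coverage_pct`,
#'   `similarity_pct`.
#' @export
align_global <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  pa <- as_protein_record(a, id = "a")
  pb <- as_protein_record(b, id = "b")
  if (pa$length == 0L || pb$length == 0L) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$sequence), Biostrings::AAString(pb$sequence),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  alignment_stats(pa$id, pb$id, sa, sb, Biostrings::score(aln),
                  longer = max(pa$length, pb$length))
}

alignment_stats <- function(id_a, id_b, sa, sb, score, longer) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  both <- ca != "-" & cb != "-"
  n_aln <- sum(both)
  ident <- if (n_aln) 100 * sum(ca[both] == cb[both]) / n_aln else 0
  bl <- blosum62()
  simil <- if (n_aln) {
    100 * sum(bl[cbind(ca[both], cb[both])] > 0) / n_aln
  } else 0
  structure(
    list(
      id_a = id_a, id_b = id_b, aligned_a = sa, aligned_b = sb,
      score = score, identity_pct = ident,
      coverage_pct = 100 * n_aln / longer, similarity_pct = simil
    ),
    class = "pairwise_alignment"
  )
}

#' Detect paralogous protein pairs
#'
#' A pair is accepted when the aligned region covers more than `coverage_min`
#' percent of the longer sequence AND more than `similarity_min` percent of
#' aligned columns are similar (strict inequalities). Similarity defaults to
#' the fraction of positive-scoring BLOSUM62 columns; set
#' `similarity = "identity"` to use percent identity instead.
#'
#' @param proteins Named character vector or list of `protein_record`s (>= 2).
#' @param coverage_min,similarity_min Acceptance thresholds (percent).
#' @param similarity `"positive"` (default) or `"identity"`.
#' @return Data frame of accepted pairs with alignment statistics.
#' @export
detect_paralogs <- function(proteins, coverage_min = 70, similarity_min = 70,
                            similarity = c("positive", "identity")) {
  similarity <- match.arg(similarity)
  proteins <- normalize_protein_set(proteins)
  if (length(proteins) < 2L) stop("need at least 2 proteins", call. = FALSE)
  ids <- names(proteins)
  pairs <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    aln <- align_global(protein_record(i, proteins[[i]]),
                        protein_record(j, proteins[[j]]))
    sim <- if (similarity == "positive") aln$similarity_pct else aln$identity_pct
    data.frame(
      id_a = i, id_b = j, coverage_pct = aln$coverage_pct,
      identity_pct = aln$identity_pct, similarity_pct = sim,
      score = aln$score, accepted = aln$coverage_pct > coverage_min & sim > similarity_min,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[out$accepted, , drop = FALSE]
}

normalize_protein_set <- function(proteins) {
  if (is.list(proteins) && all(vapply(proteins, inherits, logical(1),
                                      "protein_record"))) {
    seqs <- vapply(proteins, `[[`, character(1), "sequence")
    names(seqs) <- vapply(proteins, `[[`, character(1), "id")
    return(as.list(seqs))
  }
  if (is.null(names(proteins)) || any(names(proteins) == "")) {
    stop("proteins must be named", call. = FALSE)
  }
  as.list(proteins)
}

#' Reciprocal-best-hit orthologs
#'
#' Pair (a, b) is returned iff b is a's unique best-scoring global-alignment
#' match in `set_b` and a is b's unique best in `set_a`; score ties yield no
#' pair and are recorded.
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @return List with `pairs` (data frame id_a, id_b, score) and `ties`
#'   (character vector of ids whose best hit was tied).
#' @export
rbh_orthologs <- function(set_a, set_b) {
  set_a <- normalize_protein_set(set_a)
  set_b <- normalize_protein_set(set_b)
  if (!length(set_a) || !length(set_b)) stop("empty set", call. = FALSE)
  score <- matrix(NA_real_, length(set_a), length(set_b),
                  dimnames = list(names(set_a), names(set_b)))
  for (i in names(set_a)) {
    for (j in names(set_b)) {
      score[i, j] <- align_global(set_a[[i]], set_b[[j]])$score
    }
  }
  best_unique <- function(v) {
    m <- max(v)
    hits <- which(v >= m - 1e-9)
    if (length(hits) == 1L) names(v)[hits] else NA_character_
  }
  ties <- character()
  pairs <- list()
  for (i in names(set_a)) {
    j <- best_unique(score[i, ])
    if (is.na(j)) { ties <- c(ties, i); next }
    i_back <- best_unique(score[, j])
    if (is.na(i_back)) { ties <- c(ties, j); next }
    if (identical(i_back, i)) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(id_a = i, id_b = j, score = score[i, j],
                   stringsAsFactors = FALSE)
    }
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(id_a = character(), id_b = character(), score = numeric()),
    ties = unique(ties)
  )
}

#' Classify a duplication as tandem or segmental
#'
#' Tandem requires the two genes on the same chromosome within
#' `tandem_window` bp of each other; everything else (including different
#' chromosomes) is segmental.
#'
#' @param pair Character vector of two gene ids.
#' @param models List of `gene_model`s containing both.
#' @param tandem_window Maximum inter-gene gap for a tandem call (bp).
#' @return An object of class `duplication_call` with `pair`, `dup_type`,
#'   `same_chromosome`, `genomic_distance`.
#' @export
classify_duplication <- function(pair, models, tandem_window = 100000) {
  ids <- vapply(models, `[[`, character(1), "id")
  idx <- match(pair, ids)
  if (anyNA(idx)) {
    stop("gene(s) missing from models: ",
         paste(pair[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  g1 <- models[[idx[1]]]; g2 <- models[[idx[2]]]
  same <- identical(g1$chromosome, g2$chromosome)
  dist <- if (same) {
    max(0L, max(g1$start, g2$start) - min(g1$end, g2$end))
  } else NA_integer_
  dup_type <- if (same && dist <= tandem_window) "tandem" else "segmental"
  structure(
    list(pair = pair, dup_type = dup_type, same_chromosome = same,
         genomic_distance = dist),
    class = "duplication_call"
  )
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each protein gap becomes a 3-base gap at the corresponding codon offset.
#' The translation of each CDS must equal its ungapped protein (a trailing
#' stop codon on the CDS is tolerated and trimmed).
#'
#' @param aln A `pairwise_alignment` of the two proteins.
#' @param cds_a,cds_b Coding sequences.
#' @return List with gapped codon-level strings `a` and `b`.
#' @export
backtranslate_alignment <- function(aln, cds_a, cds_b) {
  expand <- function(prot_aln, cds, label) {
    cds <- toupper(cds)
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    if (nchar(cds) == 3 * (nchar(prot) + 1L)) {
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (genetic_code()[[last]] == "*") cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    if (nchar(cds) != 3 * nchar(prot)) {
      stop("CDS/protein length mismatch for ", label, call. = FALSE)
    }
    trans <- strsplit(translate_cds(cds), "")[[1]]
    pcols <- strsplit(prot, "")[[1]]
    bad <- which(trans != pcols)
    if (length(bad)) {
      stop("translation mismatch for ", label, " at codon ", bad[1],
           " (", split_codons(cds)[bad[1]], " -> ", trans[bad[1]],
           ", expected ", pcols[bad[1]], ")", call. = FALSE)
    }
    codons <- split_codons(cds)
    out <- character(nchar(prot_aln))
    k <- 0L
    cols <- strsplit(prot_aln, "")[[1]]
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }
  list(
    a = expand(aln$aligned_a, cds_a, aln$id_a),
    b = expand(aln$aligned_b, cds_b, aln$id_b)
  )
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Fractional synonymous/non-synonymous site counts per codon averaged over
#' the two sequences; pathway-averaged difference counts for codons differing
#' at more than one position (all orderings weighted equally, pathways
#' through stop codons excluded); Jukes-Cantor correction applied to pn and
#' ps separately. A proportion >= 3/4 makes that rate undefined.
#'
#' @param codon_aln List with codon-level strings `a`, `b` (equal length,
#'   length divisible by 3; `---` codon gaps are dropped).
#' @param neutral_tol Half-width of the neutral Ka/Ks band (default 0.05).
#' @return An object of class `kaks_result` with `N`, `S`, `Nd`, `Sd`, `pn`,
#'   `ps`, `Ka`, `Ks`, `ratio`, `selection`, `n_codons`.
#' @export
nei_gojobori <- function(codon_aln, neutral_tol = 0.05) {
  a <- toupper(codon_aln$a)
  b <- toupper(codon_aln$b)
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  ca <- split_codons(a)
  cb <- split_codons(b)
  gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (!length(ca)) stop("no ungapped codon columns", call. = FALSE)
  gc <- genetic_code()
  if (any(gc[ca] == "*") || any(gc[cb] == "*")) {
    stop("internal stop codon in alignment", call. = FALSE)
  }
  sites <- codon_sites()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  tabs <- pair_diff_tables()
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  sel <- kaks_ratio_and_selection(Ka, Ks, neutral_tol)
  structure(
    list(
      N = N, S = S, Nd = Nd, Sd = Sd, pn = pn, ps = ps,
      Ka = Ka, Ks = Ks, ratio = sel$ratio, selection = sel$selection,
      n_codons = length(ca)
    ),
    class = "kaks_result"
  )
}

#' Ka/Ks ratio and selection label
#'
#' Ratio < 1 indicates purifying (negative) selection, > 1 positive and = 1
#' neutral evolution; a tolerance band of `neutral_tol` around 1 stands in
#' for exact equality in floating point. Undefined when Ks = 0 or either
#' rate is NA.
#'
#' @param ka,ks Non-negative substitution rates (NA = undefined).
#' @param neutral_tol Neutral band half-width.
#' @return List with `ratio` and `selection` in
#'   `{purifying, positive, neutral, undefined}`.
#' @export
kaks_ratio_and_selection <- function(ka, ks, neutral_tol = 0.05) {
  if (is.na(ka) || is.na(ks)) {
    return(list(ratio = NA_real_, selection = "undefined"))
  }
  if (ka < 0 || ks < 0) stop("rates must be >= 0", call. = FALSE)
  if (ks == 0) return(list(ratio = NA_real_, selection = "undefined"))
  ratio <- ka / ks
  selection <- if (ratio < 1 - neutral_tol) "purifying"
    else if (ratio > 1 + neutral_tol) "positive" else "neutral"
  list(ratio = ratio, selection = selection)
}

#' Date a duplication from Ks under a synonymous molecular clock
#'
#' T = Ks / (2 * lambda), reported in million years (MYA). The cotton clock
#' rate is lambda = 1.5e-8 synonymous substitutions per site per year.
#'
#' @param ks Synonymous rate (substitutions per synonymous site).
#' @param lambda_rate Clock rate per site per year (> 0).
#' @return Age in MYA (unrounded; reports round to 2 decimals).
#' @export
date_duplication <- function(ks, lambda_rate = 1.5e-8) {
  if (!is.numeric(lambda_rate) || lambda_rate <= 0) {
    stop("lambda_rate must be > 0", call. = FALSE)
  }
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be >= 0", call. = FALSE)
  ks / (2 * lambda_rate) / 1e6
}
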