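# Genetic-code utilities and Nei-Gojobori (1986) codon bookkeeping.
#
# Site fractions treat a mutation to a stop codon as non-synonymous; pathway
# counting between codons differing at >1 position averages over all orderings,
# excluding pathways passing through a stop intermediate (re-weighting the
# remainder equally; if every pathway is blocked all orderings are used).

.camta_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Translate a coding sequence
#'
#' @param cds A CDS string, length divisible by 3, standard genetic code.
#' @param allow_stop Keep a trailing stop as `*`? Internal stops always error.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, allow_stop = FALSE) {
  codons <- split_codons(toupper(cds))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    stop("non-ACGT codon at codon ", which(is.na(aa))[1], call. = FALSE)
  }
  stops <- which(aa == "*")
  if (length(stops)) {
    internal <- stops[stops < length(aa)]
    if (length(internal)) {
      stop("internal stop codon at codon ", internal[1], call. = FALSE)
    }
    if (!allow_stop) {
      stop("stop codon at codon ", stops[1], call. = FALSE)
    }
  }
  paste(aa, collapse = "")
}

all_codons <- function() {
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
}

# Single-position neighbours of a codon (the 9 one-step mutants).
codon_neighbours <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  alt <- setdiff(DNA_BASES, base)
  vapply(alt, function(b) {
    paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
  }, character(1), USE.NAMES = FALSE)
}

# Fractional synonymous sites per codon position (NG86). Mutations to stop
# codons count as non-synonymous.
codon_syn_fractions <- function() {
  if (!is.null(.camta_cache$syn_frac)) return(.camta_cache$syn_frac)
  gc <- genetic_code()
  codons <- all_codons()
  frac <- matrix(NA_real_, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cdn in codons) {
    if (gc[[cdn]] == "*") next
    for (pos in 1:3) {
      nb <- codon_neighbours(cdn, pos)
      syn <- sum(gc[nb] == gc[[cdn]] & gc[nb] != "*")
      frac[cdn, pos] <- syn / 3
    }
  }
  .camta_cache$syn_frac <- frac
  frac
}

# Per-codon synonymous site count S_c (N_c = 3 - S_c).
codon_sites <- function() {
  if (!is.null(.camta_cache$sites)) return(.camta_cache$sites)
  s <- rowSums(codon_syn_fractions())
  .camta_cache$sites <- s
  s
}

# Pathway-averaged (syn, nonsyn) difference counts for one codon pair.
pathway_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1L) {
    list(pos)
  } else if (length(pos) == 2L) {
    list(pos, rev(pos))
  } else {
    list(
      pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
      pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]
    )
  }
  step_counts <- function(order) {
    cur <- c1
    sd <- nd <- 0
    blocked <- FALSE
    for (k in order) {
      nxt <- paste0(substr(cur, 1, k - 1), substr(c2, k, k),
                    substr(cur, k + 1, 3))
      if (gc[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(perms, step_counts)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  sd <- mean(vapply(res[ok], `[[`, numeric(1), "sd"))
  nd <- mean(vapply(res[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}

# 64x64 lookup matrices of pathway-averaged differences, built once.
pair_diff_tables <- function() {
  if (!is.null(.camta_cache$pair_sd)) {
    return(list(sd = .camta_cache$pair_sd, nd = .camta_cache$pair_nd))
  }
  gc <- genetic_code()
  codons <- all_codons()
  ok <- codons[gc[codons] != "*"]
  sd <- nd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (i in seq_along(ok)) {
    for (j in i:length(ok)) {
      d <- pathway_diffs(ok[i], ok[j])
      sd[ok[i], ok[j]] <- sd[ok[j], ok[i]] <- d[["sd"]]
      nd[ok[i], ok[j]] <- nd[ok[j], ok[i]] <- d[["nd"]]
    }
  }
  .camta_cache$pair_sd <- sd
  .camta_cache$pair_nd <- nd
  list(sd = sd, nd = nd)
}

#' Jukes-Cantor multiple-hit correction
#'
#' d = -(3/4) log(1 - (4/3) p); undefined (NA) for p >= 3/4.
#'
#' @param p Observed proportion of differences per site.
#' @return Corrected distance, or NA when the correction is undefined.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}
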