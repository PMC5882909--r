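# Independent oracles used across the suite. These deliberately re-derive
# everything from first principles (Biostrings' genetic code, choose(),
# explicit enumeration) rather than reusing package internals.

ORACLE_GC <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

oracle_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

random_nonstop_cds <- function(n_codons, seed) {
  nonstop <- names(ORACLE_GC)[ORACLE_GC != "*"]
  withr::with_seed(seed,
    paste(sample(nonstop, n_codons, replace = TRUE), collapse = ""))
}

# ---- NG86 oracle: brute-force site fractions and pathway enumeration ----

oracle_syn_sites <- function(codon) {
  aa <- ORACLE_GC[[codon]]
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_GC[[mut]] == aa && ORACLE_GC[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- lapply(oracle_perms(pos), function(ord) {
    cur <- c1
    sd <- nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (ORACLE_GC[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      same <- ORACLE_GC[[nxt]] == ORACLE_GC[[cur]] && ORACLE_GC[[nxt]] != "*"
      if (same) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  keep <- Filter(function(x) !x$blocked, paths)
  if (!length(keep)) keep <- paths
  c(sd = mean(vapply(keep, `[[`, numeric(1), "sd")),
    nd = mean(vapply(keep, `[[`, numeric(1), "nd")))
}

oracle_ng86 <- function(a, b) {
  ca <- oracle_codons(a)
  cb <- oracle_codons(b)
  S <- mean(c(sum(vapply(ca, oracle_syn_sites, numeric(1))),
              sum(vapply(cb, oracle_syn_sites, numeric(1)))))
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(i) oracle_pair_diffs(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[["sd"]] / S
  pn <- d[["nd"]] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[["sd"]], Nd = d[["nd"]], ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# ---- Global-alignment oracle: exhaustive enumeration with affine gaps ----

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Score a complete alignment: substitution scores minus, per maximal gap run
# in either row, (open + len * extend) -- the Biostrings cost convention.
oracle_score_alignment <- function(sa, sb, open = 10, ext = 0.5) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  subst <- sum(oracle_blosum62[cbind(ca[ca != "-" & cb != "-"],
                                     cb[ca != "-" & cb != "-"])])
  gap_cost <- function(v) {
    r <- rle(v == "-")
    sum(open + r$lengths[r$values] * ext)
  }
  subst - gap_cost(ca) - gap_cost(cb)
}

oracle_best_score <- function(a, b, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(A) && j > length(B)) {
      s <- oracle_score_alignment(paste(ca, collapse = ""),
                                  paste(cb, collapse = ""), open, ext)
      best <<- max(best, s)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, c(ca, A[i]), c(cb, B[j]))
    }
    if (i <= length(A)) rec(i + 1L, j, c(ca, A[i]), c(cb, "-"))
    if (j <= length(B)) rec(i, j + 1L, c(ca, "-"), c(cb, B[j]))
  }
  rec(1L, 1L, character(), character())
  best
}

# ---- Fisher oracle: explicit hypergeometric enumeration via choose() ----

oracle_fisher_p <- function(a, n_a, b, n_b) {
  k <- a + b
  support <- max(0, k - n_b):min(n_a, k)
  probs <- choose(n_a, support) * choose(n_b, k - support) /
    choose(n_a + n_b, k)
  pobs <- probs[support == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# ---- Motif-scan oracle: sliding window over explicit expansion sets ----

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", M = c("A", "C"), R = c("A", "G"),
  W = c("A", "T"), S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

oracle_expand <- function(motif) {
  sets <- ORACLE_IUPAC[strsplit(motif, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_scan_count <- function(seq, motifs, both_strands = TRUE) {
  found <- character()
  for (mo in motifs) {
    words <- oracle_expand(mo)
    if (both_strands) words <- unique(c(words, vapply(words, oracle_rc, "")))
    L <- nchar(mo)
    if (nchar(seq) < L) next
    for (i in 1:(nchar(seq) - L + 1)) {
      if (substr(seq, i, i + L - 1) %in% words) {
        found <- c(found, paste(i, i + L - 1))
      }
    }
  }
  length(unique(found))
}

# ---- Shared tiny fixtures ----

make_test_models <- function() {
  list(
    gene_model("gA", "chr1", "+", 1001, 2000,
               cbind(c(1001, 1401, 1801), c(1200, 1600, 2000))),
    gene_model("gB", "chr1", "-", 3001, 4000, cbind(3001, 4000)),
    gene_model("gC", "chr2", "+", 501, 900, cbind(c(501, 701), c(600, 900)))
  )
}
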