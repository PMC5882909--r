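# Domain-architecture scanning, family classification and protein properties.
#
# Consensus patterns use the field's compact notation: a literal residue,
# "X" for any residue, "[ABC]" for a residue class, and "(k)" repeating the
# preceding element k times, e.g. the cotton calmodulin-binding domain
# WXVX(2)[LVI]XKX(2)[L][R][W][R]X[KR]X(3)[FL][R]X.

#' Construct a protein record
#'
#' @param id Identifier.
#' @param sequence Amino-acid string over the 20 standard residues plus
#'   optional `X` (unknown).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_STANDARD, "X"))
  if (length(bad)) {
    stop("invalid residue(s) in ", id, ": ", paste(unique(bad), collapse = ","),
         call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence)),
    class = "protein_record"
  )
}

as_protein_record <- function(x, id = "protein") {
  if (inherits(x, "protein_record")) x else protein_record(id, x)
}

# Bundled consensus seed patterns. CaMBD and IQ follow the published cotton
# consensus; CG-1/TIG/ANK are compact in-repo seed patterns standing in for
# the Pfam profiles (out of scope), chosen so that planted synthetic domains
# are matched with zero false negatives. The CG-1 seed embeds a bipartite
# basic cluster pair so the NLS rule can fire inside its span.
CONSENSUS_PATTERNS <- c(
  CG1   = "G[KR]KRX(2)W[LIVF]X(2)KRX(10)RKKRX(2)E",
  TIG   = "[FY]XCX(2)G[LIVF]X(3)W[ST]XP",
  ANK   = "GXTPLH[LIV]AAX(2)GX[KR]",
  IQ    = "IQXXXRGXXXR",
  CaMBD = "WXVX(2)[LVI]XKX(2)[L][R][W][R]X[KR]X(3)[FL][R]X"
)

# Bipartite nuclear localization signal: two clusters of >=2 basic residues
# (K/R) separated by a 9-12 residue non-basic linker.
NLS_REGEX <- "[KR]{2,}[^KR]{9,12}[KR]{2,}"

# Parse consensus notation into element list: each element a character class
# string plus repeat count.
parse_consensus <- function(pattern) {
  tokens <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced '[' in consensus", call. = FALSE)
      cls <- chars[(i + 1):(j - 1)]
      tokens[[length(tokens) + 1L]] <- list(class = cls, rep = 1L)
      i <- j + 1L
    } else if (ch == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      k <- suppressWarnings(as.integer(paste(chars[(i + 1):(j - 1)], collapse = "")))
      if (is.na(k) || !length(tokens)) {
        stop("malformed repeat in consensus", call. = FALSE)
      }
      tokens[[length(tokens)]]$rep <- k
      i <- j + 1L
    } else if (ch == "X") {
      tokens[[length(tokens) + 1L]] <- list(class = AA_STANDARD, rep = 1L)
      i <- i + 1L
    } else if (ch %in% AA_STANDARD) {
      tokens[[length(tokens) + 1L]] <- list(class = ch, rep = 1L)
      i <- i + 1L
    } else {
      stop("unsupported consensus symbol: ", ch, call. = FALSE)
    }
  }
  tokens
}

consensus_to_regex <- function(pattern) {
  tokens <- parse_consensus(pattern)
  parts <- vapply(tokens, function(tk) {
    body <- if (length(tk$class) == 1L) tk$class else
      paste0("[", paste(tk$class, collapse = ""), "]")
    if (tk$rep > 1L) paste0(body, "{", tk$rep, "}") else body
  }, character(1))
  paste(parts, collapse = "")
}

#' Scan a protein for a named consensus pattern
#'
#' Returns every non-overlapping, left-to-right match of the registered
#' consensus as a data frame of domain hits (1-based inclusive coordinates).
#'
#' @param protein A `protein_record` or amino-acid string.
#' @param pattern_name One of `CG1`, `TIG`, `ANK`, `IQ`, `CaMBD`, `NLS`.
#' @return Data frame with columns `domain`, `start`, `end`, `matched_text`.
#' @examples
#' scan_consensus(protein_record("p", "AAIQAAARGAAARAA"), "IQ")
#' @export
scan_consensus <- function(protein, pattern_name) {
  protein <- as_protein_record(protein)
  regex <- if (pattern_name == "NLS") {
    NLS_REGEX
  } else if (pattern_name %in% names(CONSENSUS_PATTERNS)) {
    consensus_to_regex(CONSENSUS_PATTERNS[[pattern_name]])
  } else {
    stop("unknown pattern name: ", pattern_name, call. = FALSE)
  }
  empty <- data.frame(
    domain = character(), start = integer(), end = integer(),
    matched_text = character(), stringsAsFactors = FALSE
  )
  if (protein$length == 0L) return(empty)
  m <- gregexpr(regex, protein$sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    domain = pattern_name,
    start = starts,
    end = starts + lens - 1L,
    matched_text = substring(protein$sequence, starts, starts + lens - 1L),
    stringsAsFactors = FALSE
  )
}

#' Scan a protein against the full CAMTA pattern registry
#'
#' @param protein A `protein_record` or string.
#' @param patterns Pattern names to scan (default: all registered plus NLS).
#' @return Combined hit data frame sorted by start.
#' @export
scan_all_domains <- function(protein,
                             patterns = c(names(CONSENSUS_PATTERNS), "NLS")) {
  hits <- do.call(rbind, lapply(patterns, function(p) scan_consensus(protein, p)))
  hits[order(hits$start, hits$end), , drop = FALSE]
}

#' Classify CAMTA domain architecture
#'
#' A protein is called a CAMTA when it carries a CG-1 domain together with at
#' least one calmodulin-binding feature (IQ motif or CaMBD). CAMTAs lacking a
#' TIG hit are labelled `non-TIG`.
#'
#' @param hits Hit data frame from [scan_all_domains()] / [scan_consensus()].
#' @param protein The scanned `protein_record` (or string).
#' @return An object of class `domain_architecture` with fields `protein_id`,
#'   `hits`, `is_camta`, `tig_type` (`TIG`, `non-TIG` or `n/a`) and `iq_count`.
#' @export
classify_architecture <- function(hits, protein) {
  protein <- as_protein_record(protein)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  has <- function(d) any(hits$domain == d)
  iq_count <- sum(hits$domain == "IQ")
  is_camta <- has("CG1") && (iq_count > 0L || has("CaMBD"))
  tig_type <- if (!is_camta) "n/a" else if (has("TIG")) "TIG" else "non-TIG"
  structure(
    list(
      protein_id = protein$id, hits = hits, is_camta = is_camta,
      tig_type = tig_type, iq_count = iq_count
    ),
    class = "domain_architecture"
  )
}

# Average residue masses (Da) and one water; the usual protein-chemistry
# average-isotope table.
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Molecular weight of a protein (average masses)
#'
#' @param protein A `protein_record` or string; standard residues only.
#' @return Mass in Daltons.
#' @export
compute_mw <- function(protein) {
  protein <- as_protein_record(protein)
  if (protein$length == 0L) stop("empty sequence", call. = FALSE)
  res <- strsplit(protein$sequence, "")[[1]]
  bad <- which(!(res %in% names(AA_MASS)))
  if (length(bad)) {
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  sum(AA_MASS[res]) + WATER_MASS
}

# Bundled pKa table (EMBOSS-style values). pI does not aim for digit-level
# agreement with any one web server; correctness is defined by the
# charge-root condition.
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch over the termini and D, E, C, Y, H, K, R side chains.
#'
#' @param protein A `protein_record` or string.
#' @param ph pH value.
#' @return Net charge (strictly decreasing in pH).
#' @export
net_charge <- function(protein, ph) {
  protein <- as_protein_record(protein)
  res <- strsplit(protein$sequence, "")[[1]]
  counts_pos <- c(Nterm = 1, K = sum(res == "K"), R = sum(res == "R"),
                  H = sum(res == "H"))
  counts_neg <- c(Cterm = 1, D = sum(res == "D"), E = sum(res == "E"),
                  C = sum(res == "C"), Y = sum(res == "Y"))
  pos <- sum(counts_pos / (1 + 10^(ph - PKA_POSITIVE[names(counts_pos)])))
  neg <- sum(counts_neg / (1 + 10^(PKA_NEGATIVE[names(counts_neg)] - ph)))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection for the pH at which [net_charge()] crosses zero, to
#' |charge| < 1e-4; uniqueness follows from monotonicity.
#'
#' @param protein A `protein_record` or string (non-empty).
#' @return pH value.
#' @export
compute_pi <- function(protein) {
  protein <- as_protein_record(protein)
  if (protein$length == 0L) stop("empty sequence", call. = FALSE)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(protein, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

# Eisenberg consensus hydrophobicity scale.
EISENBERG <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
  E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
  M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
  Y = 0.26, V = 1.08
)

# Helical-wheel residue classes.
wheel_class <- function(res) {
  ifelse(res %in% c("D", "E"), "negative",
         ifelse(res %in% c("K", "R", "H"), "positive",
                ifelse(res %in% c("A", "V", "L", "I", "M", "F", "W", "C"),
                       "hydrophobic", "hydrophilic")))
}

#' Hydrophobic moment of a helical window
#'
#' muH = |sum_n h_n exp(i n delta)| / window on the Eisenberg scale, the
#' classic amphipathic-helix statistic (delta = 100 degrees per residue for
#' an alpha helix). An 18-residue window matches the calmodulin-binding
#' helix analysed in cotton CAMTAs.
#'
#' @param protein A `protein_record` or string.
#' @param start 1-based window start.
#' @param window Window length in residues (default 18).
#' @param delta Rotation per residue in degrees (default 100).
#' @param amphipathic_threshold muH above which the window is flagged
#'   amphipathic (default 0.2).
#' @return An object of class `helix_window_score` with `window_start`,
#'   `window_len`, `hydrophobic_moment`, `mean_hydrophobicity`,
#'   `wheel_classes` and `amphipathic`.
#' @export
hydrophobic_moment <- function(protein, start, window = 18L, delta = 100,
                               amphipathic_threshold = 0.2) {
  protein <- as_protein_record(protein)
  if (start < 1L || start + window - 1L > protein$length) {
    stop("window [", start, ", ", start + window - 1L,
         "] exceeds sequence length ", protein$length, call. = FALSE)
  }
  res <- strsplit(substring(protein$sequence, start, start + window - 1L),
                  "")[[1]]
  if (any(!(res %in% names(EISENBERG)))) {
    stop("non-standard residue in window", call. = FALSE)
  }
  h <- EISENBERG[res]
  ang <- (seq_len(window)) * delta * pi / 180
  mu <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / window
  structure(
    list(
      window_start = start, window_len = window,
      hydrophobic_moment = mu, mean_hydrophobicity = mean(h),
      wheel_classes = wheel_class(res),
      amphipathic = mu >= amphipathic_threshold
    ),
    class = "helix_window_score"
  )
}

#' Per-gene intron counts
#'
#' Introns per transcript = exon count - 1 (exons are validated and sorted
#' internally; overlapping exons are a validation error).
#'
#' @param models A list of [gene_model()] objects.
#' @return Named integer vector of intron counts.
#' @export
intron_counts <- function(models) {
  out <- vapply(models, function(gm) {
    gm <- validate_gene_model(gm)
    nrow(gm$exons) - 1L
  }, integer(1))
  names(out) <- vapply(models, `[[`, character(1), "id")
  out
}
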