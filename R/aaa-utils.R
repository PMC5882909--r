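# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific child seed from a top-level seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, scan = 23L, kaks = 37L, coexpress = 53L,
    motifs = 71L, traits = 97L, control = 113L
  )
  off <- offsets[[stage]] %||% 1L
  as.integer((as.numeric(seed) * 1103 + off) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s),
                       "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
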