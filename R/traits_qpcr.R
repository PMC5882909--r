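# qRT-PCR relative quantification (2^-ddCt), the 1/dCt expression proxy and
# Pearson correlation of expression with fiber-quality traits
# (FL, FS, UR, MIC, BN, BW).

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicate Ct values are averaged on the Ct scale before the
#' exponential transform. dCt = Ct(target) - Ct(reference); ddCt = dCt -
#' dCt(calibrator); fold change = 2^-ddCt.
#'
#' @param ct_target,ct_ref Ct values (vectors of technical replicates are
#'   averaged).
#' @param calibrator_dct dCt of the calibrator sample.
#' @return List with `dct`, `ddct`, `fold`.
#' @export
delta_delta_ct <- function(ct_target, ct_ref, calibrator_dct = 0) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_ref))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  dct <- mean(ct_target) - mean(ct_ref)
  ddct <- dct - calibrator_dct
  list(dct = dct, ddct = ddct, fold = 2^(-ddct))
}

#' Expression proxy 1/dCt
#'
#' The reciprocal-dCt proxy used to plot expression against trait values.
#' Implemented literally, including its sign flip for negative dCt (target
#' more abundant than the reference), which triggers a warning.
#'
#' @param dct Numeric vector of dCt values (nonzero).
#' @return 1/dct, preserving names and order.
#' @export
expression_proxy <- function(dct) {
  if (any(dct == 0)) {
    stop("dCt of 0 gives an undefined 1/dCt proxy (genotype ",
         which(dct == 0)[1], ")", call. = FALSE)
  }
  if (any(dct < 0)) {
    warning("negative dCt values flip the sign of the 1/dCt proxy")
  }
  1 / dct
}

#' Pearson correlation with a two-sided p-value
#'
#' p from the t transform t = r * sqrt((n - 2) / (1 - r^2)) against the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, equal length >= 3, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlate an expression proxy with every trait
#'
#' Genotypes are matched by name; missing values are handled
#' pairwise-complete and the per-trait n is reported. No multiplicity
#' correction is applied by default (set `adjust = "BH"` for
#' Benjamini-Hochberg).
#'
#' @param proxies Named numeric vector of per-genotype expression proxies.
#' @param traits Data frame with a `genotype` column and one numeric column
#'   per trait.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `trait`, `n`, `r`, `p` (NA rows flag traits with
#'   fewer than 3 complete pairs).
#' @export
trait_scan <- function(proxies, traits, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!("genotype" %in% names(traits))) {
    stop("traits table needs a 'genotype' column", call. = FALSE)
  }
  common <- intersect(names(proxies), traits$genotype)
  if (!length(common)) stop("no shared genotypes", call. = FALSE)
  traits <- traits[match(common, traits$genotype), , drop = FALSE]
  x <- proxies[common]
  trait_cols <- setdiff(names(traits), "genotype")
  rows <- lapply(trait_cols, function(tr) {
    y <- traits[[tr]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      return(data.frame(trait = tr, n = sum(ok), r = NA_real_, p = NA_real_))
    }
    res <- pearson_with_p(x[ok], y[ok])
    data.frame(trait = tr, n = res$n, r = res$r, p = res$p)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
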