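# Neighbor-joining trees with optional column-resampling bootstrap.
# A desk-scale, distance-based stand-in for full ML phylogenetics: exact on
# additive distance matrices, which is what the tests exercise.

#' Neighbor-joining tree with optional bootstrap support
#'
#' Standard Saitou-Nei neighbor joining over a symmetric distance matrix.
#' When an alignment is supplied, p-distances are computed from it and
#' bootstrap support is estimated by resampling alignment columns with
#' replacement; support = percent of replicates containing each internal
#' bipartition. Negative branch-length estimates are clamped to zero and
#' flagged.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and taxon
#'   dimnames; may be NULL when `alignment` is given.
#' @param bootstrap_reps Bootstrap replicates (used only with `alignment`).
#' @param alignment Optional named character vector of equal-length aligned
#'   sequences.
#' @param seed Seed for bootstrap resampling.
#' @return An object of class `distance_tree`: list with `tree` (an
#'   \pkg{ape} `phylo`), `supports` (percent per internal node, or NULL) and
#'   `negative_clamped` flag.
#' @export
nj_tree <- function(distances = NULL, bootstrap_reps = 1000,
                    alignment = NULL, seed = 1) {
  if (is.null(distances)) {
    if (is.null(alignment)) stop("need distances or an alignment", call. = FALSE)
    distances <- p_distance_matrix(alignment)
  }
  check_distance_matrix(distances)
  built <- nj_build(distances)
  supports <- NULL
  if (!is.null(alignment)) {
    L <- unique(nchar(alignment))
    if (length(L) != 1L) stop("alignment lengths differ", call. = FALSE)
    mat <- do.call(rbind, strsplit(alignment, ""))
    rownames(mat) <- names(alignment)
    boots <- with_seed(seed, lapply(seq_len(bootstrap_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      nj_build(p_distance_matrix_from_mat(mat[, cols, drop = FALSE]))$tree
    }))
    counts <- ape::prop.clades(built$tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    supports <- 100 * counts / bootstrap_reps
  }
  structure(
    list(tree = built$tree, supports = supports,
         negative_clamped = built$clamped),
    class = "distance_tree"
  )
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L) {
    stop("distances must be a square matrix over >= 2 taxa", call. = FALSE)
  }
  if (is.null(rownames(d))) stop("distance matrix needs taxon names", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is asymmetric beyond 1e-9", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal", call. = FALSE)
  invisible(d)
}

# Core NJ, assembled as newick then parsed by ape (keeps node bookkeeping
# in one battle-tested place).
nj_build <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 2L) {
    h <- clamp(d[1, 2] / 2)
    nwk <- paste0("(", labels[1], ":", fmt(h), ",", labels[2], ":", fmt(h), ");")
    return(list(tree = ape::read.tree(text = nwk), clamped = clamped))
  }
  sub <- as.list(labels)
  D <- d
  while (length(sub) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(k); j <- max(k)
    vi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_sub <- paste0("(", sub[[i]], ":", fmt(vi), ",", sub[[j]], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    D <- D2
    sub <- c(sub[keep], list(new_sub))
  }
  v1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", sub[[1]], ":", fmt(v1), ",", sub[[2]], ":", fmt(v2),
                ",", sub[[3]], ":", fmt(v3), ");")
  list(tree = ape::read.tree(text = nwk), clamped = clamped)
}

#' Pairwise p-distance matrix from aligned sequences
#'
#' Proportion of differing columns among columns where both sequences are
#' ungapped.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Symmetric distance matrix.
#' @export
p_distance_matrix <- function(alignment) {
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  p_distance_matrix_from_mat(mat)
}

p_distance_matrix_from_mat <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    }
  }
  d
}
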