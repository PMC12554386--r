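# Alpha diversity, Bray-Curtis ordination and ANOSIM group testing.
# Implemented directly from the definitions; vegan/cmdscale serve only as
# independent oracles in the test suite.

#' Shannon diversity (natural log)
#'
#' `H = -sum p_k ln p_k` over the positive proportions of a count (or
#' proportion) vector. Reported in nats; the study's printed values (5.8-6.2)
#' are only interpretable under the natural log.
#'
#' @param counts Non-negative vector with at least one positive entry.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) abort_arg("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) abort_arg("zero vector has no diversity")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj)` on raw counts (no
#' rarefying; the optional `rarefy_to` subsamples each column first).
#'
#' @param table A `community_table` (or a non-negative matrix with sample
#'   columns).
#' @param rarefy_to Optional depth to subsample each sample to (without
#'   replacement) before computing distances; default off.
#' @param seed Seed used only when `rarefy_to` is set.
#' @return Symmetric dissimilarity matrix in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(table, rarefy_to = NULL, seed = NULL) {
  x <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (ncol(x) < 2L) abort_arg("need >= 2 samples")
  if (any(colSums(x) == 0)) abort_arg("all-zero sample column")
  if (!is.null(rarefy_to)) {
    x <- with_seed(seed, apply(x, 2L, rarefy_column, depth = rarefy_to))
  }
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(abs(x[, i] - x[, j])) / sum(x[, i] + x[, j])
    }
  }
  d
}

rarefy_column <- function(col, depth) {
  tot <- sum(col)
  if (tot <= depth) return(col)
  drawn <- sample.int(tot, depth)
  cum <- cumsum(col)
  tabulate(findInterval(drawn - 1L, c(0, cum), rightmost.closed = FALSE),
           nbins = length(col))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-d^2/2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for positive eigenvalues. Negative
#' eigenvalues are reported as-is (no Lingoes/Cailliez correction);
#' `proportion_explained` is computed over the positive eigenvalues.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes Number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return Object of class `ordination_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending) and
#'   `proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    abort_arg("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-8)) abort_arg("dissimilarity matrix must have a zero diagonal")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values) * 1e-12 & values > 0)
  if (length(pos) == 0L) abort_arg("no positive eigenvalues; degenerate input")
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(values[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = values,
                 proportion_explained = values[pos[seq_len(k)]] / sum(values[pos])),
            class = "ordination_result")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation:
#' `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n(n-1)/2` pairs, mid-ranks for ties. The p-value is
#' `(1 + #(permuted R >= observed R)) / (1 + n_perm)` under random
#' permutation of group labels (never exactly 0).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return Object of class `anosim_result`: list with `R`, `p`, `n_perm`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) abort_arg("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) abort_arg("ANOSIM needs >= 2 groups")
  if (any(sizes < 2L)) {
    abort_arg("every group needs >= 2 samples (singleton group: %s)",
              paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ut <- upper.tri(d)
  ranks <- rank(d[ut], ties.method = "average")
  m <- length(ranks)
  pair_idx <- which(ut, arr.ind = TRUE)
  r_stat <- function(g) {
    within <- g[pair_idx[, 1L]] == g[pair_idx[, 2L]]
    (mean(ranks[!within]) - mean(ranks[within])) / (m / 2)
  }
  r_obs <- r_stat(groups)
  p <- with_seed(seed, {
    ge <- 0L
    for (k in seq_len(n_perm)) {
      if (r_stat(sample(groups)) >= r_obs) ge <- ge + 1L
    }
    (1 + ge) / (1 + n_perm)
  })
  structure(list(R = r_obs, p = p, n_perm = n_perm), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n", x$R, x$p, x$n_perm))
  invisible(x)
}
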