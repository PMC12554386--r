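# Independent oracles: brute-force graph algorithms and quadrature for the
# neutral-model occurrence probability. These deliberately avoid the code
# paths (igraph, pbeta) they are used to check.

net_adjacency <- function(net) {
  ids <- net$nodes$otu_id
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0L) {
    for (k in seq_len(nrow(net$edges))) {
      i <- net$edges$otu_a[k]; j <- net$edges$otu_b[k]
      a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

# Mean shortest-path length (hops) over connected pairs, plus component count.
floyd_warshall_gd <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      lower <- nd < d[i, ]
      d[i, lower] <- nd[lower]
    }
  }
  finite <- is.finite(d) & upper.tri(d)
  gd <- if (any(finite)) mean(d[finite]) else NA_real_
  # components by reachability
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cc <- cc + 1L
      comp[is.finite(d[i, ])] <- cc
    }
  }
  list(gd = gd, components = cc)
}

# Newman-Girvan modularity of a membership vector on an unweighted graph.
modularity_of <- function(adj, membership) {
  m2 <- sum(adj)          # 2m
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(adj[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

# All set partitions of n elements as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (c in seq_len(maxc + 1L)) rec(c(prefix, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

best_modularity_exhaustive <- function(adj) {
  best <- -Inf
  for (p in all_partitions(nrow(adj))) best <- max(best, modularity_of(adj, p))
  best
}

best_modularity_bipartitions <- function(adj) {
  n <- nrow(adj)
  best <- modularity_of(adj, rep(1L, n))
  for (mask in seq_len(2^(n - 1L) - 1L)) {
    membership <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    best <- max(best, modularity_of(adj, membership))
  }
  best
}

# Occurrence probability 1 - I_d(Nm*p, Nm*(1-p)) by direct quadrature of the
# beta density over the upper tail [d, 1]. Avoids the x = 0 singularity
# entirely (the integrand is smooth on [d, 1] whenever b = Nm*(1-p) > 1, the
# regime of every test grid); integrates in log space for stability.
occurrence_prob_quadrature <- function(p, Nm, d) {
  a <- Nm * p
  b <- Nm * (1 - p)
  stopifnot(b > 1)
  lb <- lbeta(a, b)
  f <- function(x) exp((a - 1) * log(x) + (b - 1) * log1p(-x) - lb)
  stats::integrate(f, d, 1, rel.tol = 1e-13, abs.tol = 1e-13,
                   subdivisions = 5000L)$value
}
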