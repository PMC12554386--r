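# Small fixture builders used across the suite. Everything is generated in
# code; no stored data files.

make_table <- function(mat, groups = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("OTU%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  if (is.null(groups)) {
    groups <- stats::setNames(rep(c("A", "B"), length.out = ncol(mat)), colnames(mat))
  } else if (is.null(names(groups))) {
    groups <- stats::setNames(groups, colnames(mat))
  }
  community_table(mat, groups)
}

random_table <- function(n_otus, n_samples, seed, lambda_pois = 8, groups = NULL) {
  set.seed(seed)
  mat <- matrix(rpois(n_otus * n_samples, lambda_pois), n_otus, n_samples)
  mat[cbind(seq_len(n_otus), sample(n_samples, n_otus, replace = TRUE))] <- lambda_pois + 1L
  make_table(mat, groups)
}

# Build a co_network directly from an unordered edge list over node ids.
make_net <- function(node_ids, edge_pairs, rho = NULL, guild = NULL, abundance = NULL) {
  nodes <- data.frame(otu_id = node_ids, stringsAsFactors = FALSE)
  nodes$abundance <- if (is.null(abundance)) rev(seq_along(node_ids)) else abundance
  if (!is.null(guild)) nodes$guild <- guild
  if (length(edge_pairs) == 0L) {
    edges <- data.frame(otu_a = character(0), otu_b = character(0),
                        rho = numeric(0), q = numeric(0), sign = character(0))
  } else {
    ep <- do.call(rbind, edge_pairs)
    r <- if (is.null(rho)) rep(0.9, nrow(ep)) else rho
    edges <- data.frame(otu_a = ep[, 1L], otu_b = ep[, 2L], rho = r,
                        q = rep(1e-4, nrow(ep)),
                        sign = ifelse(r >= 0, "+", "-"), stringsAsFactors = FALSE)
  }
  co_network(nodes, edges)
}

random_net <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  make_net(ids, lapply(which(keep), function(i) pairs[i, ]))
}
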