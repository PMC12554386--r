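# Correlation-based co-occurrence networks on the most abundant OTUs, with
# the topology metrics used to compare treatments (avgK, density, GD,
# modularity, edge-sign and guild edge-type proportions). Graph algorithms
# are delegated to igraph behind this module's contract; independent oracles
# live in the test suite.

#' Construct a co-occurrence network record
#'
#' Low-level constructor used by [build_network()] and by tests that need a
#' network with known structure. Validates the invariants: no self edges, no
#' duplicate unordered pairs, all endpoints among the nodes.
#'
#' @param nodes Data frame with columns `otu_id`, optional `guild`,
#'   `abundance`.
#' @param edges Data frame with columns `otu_a`, `otu_b`, `rho`, `q`, `sign`.
#' @param parameters Named list of construction parameters.
#' @return Object of class `co_network`.
#' @export
co_network <- function(nodes, edges, parameters = list()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!"otu_id" %in% names(nodes)) abort_arg("nodes need an otu_id column")
  if (nrow(edges) > 0L) {
    if (!all(c("otu_a", "otu_b") %in% names(edges))) {
      abort_arg("edges need otu_a and otu_b columns")
    }
    if (any(edges$otu_a == edges$otu_b)) abort_arg("self-edges are not allowed")
    key <- paste(pmin(edges$otu_a, edges$otu_b), pmax(edges$otu_a, edges$otu_b))
    if (anyDuplicated(key)) abort_arg("duplicate unordered edge pairs")
    stray <- setdiff(c(edges$otu_a, edges$otu_b), nodes$otu_id)
    if (length(stray)) abort_arg("edge endpoints missing from nodes: %s",
                                 paste(stray, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, parameters = parameters),
            class = "co_network")
}

#' Build a co-occurrence network for one group of samples
#'
#' Keeps the `n_top` most abundant OTUs, drops OTUs below the prevalence
#' cutoff and zero-variance rows (with a warning), computes all-pairs rank
#' correlations on per-sample relative abundances, converts them to p-values
#' (t approximation on the correlation), adjusts across all tested pairs and
#' keeps edges with `|rho| >= r_threshold` and adjusted `p < p_threshold`.
#' Correlation sign is retained as an edge attribute.
#'
#' @param table A `community_table` restricted to the group (>= 5 samples).
#' @param n_top Number of most-abundant OTUs to consider.
#' @param method `"spearman"` or `"pearson"`.
#' @param r_threshold Minimum absolute correlation.
#' @param p_threshold Maximum adjusted p-value (strict).
#' @param adjustment Multiple-testing adjustment (`stats::p.adjust` method).
#' @param min_prevalence Minimum fraction of samples with nonzero count.
#' @return A [co_network()]; nodes are all OTUs that entered testing.
#' @export
build_network <- function(table, n_top = 300, method = c("spearman", "pearson"),
                          r_threshold = 0.6, p_threshold = 0.05,
                          adjustment = "BH", min_prevalence = 0.2) {
  stopifnot(inherits(table, "community_table"))
  method <- match.arg(method)
  n <- ncol(table$counts)
  if (n < 5L) abort_arg("network construction needs >= 5 samples (correlations meaningless)")
  top <- filter_top_n(table, min(n_top, nrow(table$counts)))
  prev <- rowMeans(top$counts > 0)
  top_counts <- top$counts[prev >= min_prevalence, , drop = FALSE]
  if (nrow(top_counts) < 2L) abort_arg("fewer than 2 OTUs pass the prevalence filter")
  rel <- sweep(top_counts, 2L, colSums(table$counts)[colnames(top_counts)], "/")
  zero_var <- apply(rel, 1L, stats::sd) == 0
  if (any(zero_var)) {
    warning(sprintf("excluding %d zero-variance OTU(s) from correlation testing",
                    sum(zero_var)), call. = FALSE)
    rel <- rel[!zero_var, , drop = FALSE]
  }
  ids <- rownames(rel)
  m <- nrow(rel)
  cmat <- stats::cor(t(rel), method = method)
  iu <- which(upper.tri(cmat), arr.ind = TRUE)
  rho <- cmat[upper.tri(cmat)]
  # t approximation for the correlation null; exact at rho = +/-1 (p -> 0)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  qval <- stats::p.adjust(pval, method = adjustment)
  keep <- abs(rho) >= r_threshold & qval < p_threshold
  edges <- data.frame(otu_a = ids[iu[keep, 1L]], otu_b = ids[iu[keep, 2L]],
                      rho = rho[keep], q = qval[keep],
                      sign = ifelse(rho[keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(otu_id = ids, abundance = rowSums(top_counts[ids, , drop = FALSE]),
                      stringsAsFactors = FALSE, row.names = NULL)
  co_network(nodes, edges,
             parameters = list(method = method, r_threshold = r_threshold,
                               p_threshold = p_threshold, adjustment = adjustment,
                               min_prevalence = min_prevalence, n_top = n_top,
                               n_samples = n))
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("otu_a", "otu_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$otu_id, stringsAsFactors = FALSE))
  g
}

#' Topology metrics of a co-occurrence network
#'
#' Average degree `avgK = 2E/V`, density `2E/(V(V-1))`, average shortest-path
#' length `gd` in hops over connected vertex pairs only (`NA` with a
#' diagnostic when the network has no edges), number of connected components,
#' modularity `Q` of the partition found by deterministic greedy (fast-greedy)
#' modularity maximization on the unsigned graph, and the fraction of
#' positive-sign edges.
#'
#' @param net A [co_network()] with at least 2 nodes.
#' @return Object of class `topology_metrics`: list with `n_nodes`,
#'   `n_edges`, `avgK`, `density`, `gd`, `modularity`, `pct_positive`,
#'   `component_count`.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "co_network"))
  v <- nrow(net$nodes)
  if (v < 2L) abort_arg("topology needs >= 2 nodes")
  e <- nrow(net$edges)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (e == 0L) {
    gd <- NA_real_
    q <- NA_real_
    message("topology: edgeless network, gd and modularity undefined")
  } else {
    gd <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    cl <- igraph::cluster_fast_greedy(g)
    q <- igraph::modularity(cl)
  }
  pct_pos <- if (e == 0L) NA_real_ else mean(net$edges$sign == "+")
  structure(list(n_nodes = v, n_edges = e,
                 avgK = 2 * e / v,
                 density = 2 * e / (v * (v - 1)),
                 gd = gd, modularity = q,
                 pct_positive = pct_pos,
                 component_count = comp$no),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf("topology: %d nodes, %d edges | avgK %.2f, D %.3f, GD %s, Q %s, %.1f%% positive, %d component(s)\n",
              x$n_nodes, x$n_edges, x$avgK, x$density,
              ifelse(is.na(x$gd), "NA", sprintf("%.2f", x$gd)),
              ifelse(is.na(x$modularity), "NA", sprintf("%.2f", x$modularity)),
              100 * ifelse(is.na(x$pct_positive), 0, x$pct_positive), x$component_count))
  invisible(x)
}

#' Guild composition of network edges
#'
#' Restricts the network to the `scope_n` most abundant guild-labelled
#' (generalist or specialist) nodes, drops edges with a non-significant or
#' out-of-scope endpoint, and returns the fractions of
#' generalist-generalist (`gg`), generalist-specialist (`gs`) and
#' specialist-specialist (`ss`) edges among the remainder.
#'
#' @param net A [co_network()] whose nodes carry an `abundance` column.
#' @param guilds A [classify_guilds()] result.
#' @param scope_n How many guild-labelled OTUs (by abundance) to keep. The
#'   source study is ambiguous between 100 and 150, so no default is claimed.
#' @return Object of class `edge_type_proportions`: list `gg`, `gs`, `ss`,
#'   `n_edges_classified`.
#' @export
edge_type_proportions <- function(net, guilds, scope_n) {
  stopifnot(inherits(net, "co_network"), inherits(guilds, "guild_classification"))
  if (missing(scope_n) || !is.numeric(scope_n) || scope_n < 2) {
    abort_arg("scope_n (number of most-abundant guild-labelled OTUs) is required, >= 2")
  }
  lab <- stats::setNames(guilds$guild, guilds$otu_id)
  nodes <- net$nodes
  nodes$guild <- lab[nodes$otu_id]
  labelled <- nodes[!is.na(nodes$guild) & nodes$guild %in% c("generalist", "specialist"), ]
  if (nrow(labelled) == 0L) abort_arg("no guild-labelled nodes in the network")
  labelled <- labelled[order(-labelled$abundance, labelled$otu_id), ]
  scope <- utils::head(labelled$otu_id, scope_n)
  e <- net$edges
  ga <- lab[e$otu_a]
  gb <- lab[e$otu_b]
  in_scope <- e$otu_a %in% scope & e$otu_b %in% scope &
    ga %in% c("generalist", "specialist") & gb %in% c("generalist", "specialist")
  if (!any(in_scope)) {
    abort_arg("no edges with both endpoints guild-labelled within scope_n = %d", scope_n)
  }
  ga <- ga[in_scope]; gb <- gb[in_scope]
  n_gg <- sum(ga == "generalist" & gb == "generalist")
  n_ss <- sum(ga == "specialist" & gb == "specialist")
  n_gs <- sum(in_scope) - n_gg - n_ss
  tot <- sum(in_scope)
  structure(list(gg = n_gg / tot, gs = n_gs / tot, ss = n_ss / tot,
                 n_edges_classified = tot, scope_n = scope_n),
            class = "edge_type_proportions")
}

#' Write a network in GraphML for external viewers (Gephi-compatible)
#' @param net A [co_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "co_network"))
  g <- as_igraph(net)
  if (nrow(net$edges) > 0L) {
    igraph::E(g)$rho <- net$edges$rho
    igraph::E(g)$sign <- net$edges$sign
  }
  if (!is.null(net$nodes$guild)) igraph::V(g)$guild <- net$nodes$guild
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
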