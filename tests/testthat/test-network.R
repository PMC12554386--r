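test_that("build_network recovers planted pairs and respects thresholds", {
  set.seed(33)
  mat <- t(replicate(12, sample.int(400, 18)))
  tab <- make_table(mat, rep("G", 18))
  planted <- inject_correlated_pair(tab, "OTU01", "OTU02", "+", 1, seed = 4)
  # equalize library sizes with a filler row so the comonotone count ranks
  # survive the per-sample relative-abundance transform exactly
  cs <- colSums(planted$counts)
  filler <- max(cs) + 50L - cs
  m_eq <- rbind(planted$counts, OTU13 = filler)
  planted_eq <- make_table(m_eq, rep("G", 18))
  net <- build_network(planted_eq, n_top = 13, r_threshold = 0.6)
  hit <- (net$edges$otu_a == "OTU01" & net$edges$otu_b == "OTU02") |
         (net$edges$otu_a == "OTU02" & net$edges$otu_b == "OTU01")
  expect_true(any(hit))
  expect_equal(net$edges$rho[hit], 1)
  expect_equal(net$edges$sign[hit], "+")

  # impossible threshold empties the edge set but keeps nodes
  empty <- build_network(planted, n_top = 12, r_threshold = 1.01)
  expect_equal(nrow(empty$edges), 0L)
  expect_gt(nrow(empty$nodes), 0L)

  expect_error(build_network(subset_table(tab, samples = sample_ids(tab)[1:4])),
               ">= 5 samples")

  # zero-variance OTUs (constant relative abundance) are excluded with warning
  a <- 10L + seq_len(18)
  mz <- rbind(OTUa = a, OTUb = 60L - a, OTUc = rep(40L, 18))
  tabz <- make_table(mz, rep("G", 18))
  expect_warning(netz <- build_network(tabz, n_top = 3, min_prevalence = 0),
                 "zero-variance")
  expect_false("OTUc" %in% netz$nodes$otu_id)
  expect_equal(netz$edges$rho, -1)
  expect_equal(netz$edges$sign, "-")
})

test_that("network construction is invariant to OTU order", {
  tab <- random_table(20, 12, seed = 8, groups = rep("G", 12))
  net1 <- build_network(tab, n_top = 20, r_threshold = 0.4)
  set.seed(2)
  perm <- sample(rownames(tab$counts))
  net2 <- build_network(make_table(tab$counts[perm, ], tab$groups), n_top = 20,
                        r_threshold = 0.4)
  key <- function(net) sort(paste(pmin(net$edges$otu_a, net$edges$otu_b),
                                  pmax(net$edges$otu_a, net$edges$otu_b)))
  expect_identical(key(net1), key(net2))
})

test_that("co_network constructor enforces edge invariants", {
  expect_error(make_net(c("a", "b"), list(c("a", "a"))), "self-edges")
  expect_error(make_net(c("a", "b"), list(c("a", "b"), c("b", "a"))), "duplicate")
  expect_error(make_net(c("a", "b"), list(c("a", "c"))), "missing from nodes")
})

test_that("topology matches closed forms on reference graphs", {
  k5 <- make_net(letters[1:5], combn(letters[1:5], 2, simplify = FALSE))
  t5 <- topology(k5)
  expect_equal(t5$avgK, 4)
  expect_equal(t5$density, 1)
  expect_equal(t5$gd, 1)
  expect_equal(t5$component_count, 1L)
  expect_equal(t5$pct_positive, 1)

  p3 <- make_net(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  t3 <- topology(p3)
  expect_equal(t3$avgK, 4 / 3)
  expect_equal(t3$density, 2 / 3)
  expect_equal(t3$gd, 4 / 3)

  tri2 <- make_net(letters[1:6],
                   list(c("a", "b"), c("b", "c"), c("a", "c"),
                        c("d", "e"), c("e", "f"), c("d", "f")))
  t6 <- topology(tri2)
  expect_equal(t6$density, 0.4)
  expect_equal(t6$gd, 1)
  expect_equal(t6$component_count, 2L)
  expect_equal(t6$modularity, 0.5)
  expect_equal(t6$modularity, best_modularity_exhaustive(net_adjacency(tri2)))

  # edgeless network: gd undefined but other metrics returned
  iso <- make_net(c("a", "b", "c"), list())
  expect_message(ti <- topology(iso), "edgeless")
  expect_true(is.na(ti$gd))
  expect_equal(ti$avgK, 0)
  expect_equal(ti$component_count, 3L)
})

test_that("avgK/density identities and brute-force gd hold on random graphs", {
  for (s in 1:25) {
    net <- random_net(n_nodes = 5L + (s * 7L) %% 16L,
                      p_edge = 0.1 + 0.4 * (s %% 5) / 5, seed = s)
    tp <- topology(net)
    expect_equal(tp$avgK, 2 * tp$n_edges / tp$n_nodes)
    expect_equal(tp$density, 2 * tp$n_edges / (tp$n_nodes * (tp$n_nodes - 1)))
    fw <- floyd_warshall_gd(net_adjacency(net))
    expect_equal(tp$gd, fw$gd)
    expect_equal(tp$component_count, fw$components)
    if (tp$n_edges > 0) expect_gte(tp$modularity, 0)
  }
})

test_that("greedy modularity is near the exhaustive optimum on planted graphs", {
  # greedy is a heuristic: on arbitrary random graphs require closeness to
  # the exhaustive optimum (n <= 8), on planted two-clique graphs the tight
  # 0.02 bound below
  for (s in 1:5) {
    net <- random_net(7, 0.35, seed = 100 + s)
    if (nrow(net$edges) == 0) next
    q_best <- best_modularity_exhaustive(net_adjacency(net))
    expect_gte(topology(net)$modularity, q_best - 0.1)
  }
  tri2 <- make_net(letters[1:6],
                   list(c("a", "b"), c("b", "c"), c("a", "c"),
                        c("d", "e"), c("e", "f"), c("d", "f")))
  expect_gte(topology(tri2)$modularity,
             best_modularity_exhaustive(net_adjacency(tri2)) - 0.02)
  # planted two-clique graph on 12 nodes: bipartition search finds the optimum
  ids <- sprintf("N%02d", 1:12)
  cl1 <- combn(ids[1:6], 2, simplify = FALSE)
  cl2 <- combn(ids[7:12], 2, simplify = FALSE)
  net2 <- make_net(ids, c(cl1, cl2, list(c(ids[6], ids[7]))))
  q_best <- best_modularity_bipartitions(net_adjacency(net2))
  expect_gte(topology(net2)$modularity, q_best - 0.02)
})

test_that("edge type proportions follow endpoint guilds", {
  guilds <- structure(
    data.frame(otu_id = c("g1", "g2", "g3", "s1", "s2", "s3", "n1"),
               B_obs = 1, low_ci = 0, upp_ci = 2,
               guild = c("generalist", "generalist", "generalist",
                         "specialist", "specialist", "specialist",
                         "non_significant"),
               stringsAsFactors = FALSE),
    class = c("guild_classification", "data.frame"),
    n_perm = 100, r = 10, scheme = "within_sample_shuffle", seed = 1)

  allg <- make_net(c("g1", "g2", "g3"),
                   list(c("g1", "g2"), c("g2", "g3"), c("g1", "g3")))
  et <- edge_type_proportions(allg, guilds, scope_n = 10)
  expect_equal(et$gg, 1); expect_equal(et$gs, 0); expect_equal(et$ss, 0)

  # star: specialist centre, generalist leaves -> all edges G-S
  star <- make_net(c("s1", "g1", "g2", "g3"),
                   list(c("s1", "g1"), c("s1", "g2"), c("s1", "g3")))
  et2 <- edge_type_proportions(star, guilds, scope_n = 10)
  expect_equal(et2$gs, 1)

  # dense specialist cluster dominates; non_significant endpoints excluded
  mix <- make_net(c("s1", "s2", "s3", "g1", "n1"),
                  list(c("s1", "s2"), c("s2", "s3"), c("s1", "s3"),
                       c("g1", "s1"), c("n1", "g1")))
  et3 <- edge_type_proportions(mix, guilds, scope_n = 10)
  expect_equal(et3$n_edges_classified, 4L)
  expect_gt(et3$ss, et3$gs); expect_gt(et3$ss, et3$gg)
  expect_equal(et3$gg + et3$gs + et3$ss, 1, tolerance = 1e-9)

  # scope_n restricts to the most abundant labelled nodes
  et4 <- edge_type_proportions(mix, guilds, scope_n = 3)
  expect_lte(et4$n_edges_classified, et3$n_edges_classified)

  nolabel <- make_net(c("n1", "g1"), list(c("n1", "g1")))
  expect_error(edge_type_proportions(nolabel, guilds, scope_n = 5), "no edges")
  expect_error(edge_type_proportions(allg, guilds), "scope_n")
})
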