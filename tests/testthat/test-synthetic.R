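test_that("metacommunity generator is deterministic, sorted, and handles sigma = 0", {
  m1 <- simulate_metacommunity(500, 0, 1.5, seed = 42)
  m2 <- simulate_metacommunity(500, 0, 1.5, seed = 42)
  expect_identical(m1$p, m2$p)
  expect_equal(sum(m1$p), 1)
  expect_true(all(diff(m1$p) <= 0))
  expect_true(all(m1$p > 0))

  unif <- simulate_metacommunity(10, 0, 0, seed = 1)
  expect_equal(unname(unif$p), rep(0.1, 10))
  expect_error(simulate_metacommunity(1, seed = 1), ">= 2")
})

test_that("neutral sampler hits its limit cases", {
  meta <- simulate_metacommunity(50, 0, 1, seed = 7)

  # m = 1: every death replaced by an immigrant, so the local community is an
  # iid draw from p and composition tracks the metacommunity
  cfg <- neutral_sim_config(N = 5000, m = 1, burn_in_steps = 5000,
                            depth = 1e5, seed = 7)
  counts <- simulate_neutral_sample(meta, cfg)
  expect_equal(sum(counts), 1e5)
  expect_gt(cor(counts / sum(counts), meta$p), 0.99)
  expect_lt(max(abs(counts / sum(counts) - meta$p)), 0.02)

  # m = 0 with a long burn-in: pure drift fixes a single taxon
  cfg0 <- neutral_sim_config(N = 30, m = 0, burn_in_steps = 20000,
                             depth = 1000, seed = 11)
  counts0 <- simulate_neutral_sample(meta, cfg0)
  expect_equal(sum(counts0 > 0), 1L)

  # every generated column sums to its configured depth exactly
  for (s in 1:3) {
    cfg_s <- neutral_sim_config(N = 100, m = 0.3, burn_in_steps = 1000,
                                depth = 2345, seed = s)
    expect_equal(sum(simulate_neutral_sample(meta, cfg_s)), 2345)
  }
})

test_that("neutral occurrence frequency increases with metacommunity abundance", {
  meta <- simulate_metacommunity(200, 0, 1.5, seed = 21)
  set.seed(21)
  counts <- sapply(1:30, function(j) {
    f <- assemblage:::neutral_local_freq(meta$p, 1000, 0.1, 10000)
    as.vector(rmultinom(1, 10000, f))
  })
  rownames(counts) <- names(meta$p)
  f_obs <- rowMeans(counts > 0)
  expect_gt(cor(f_obs, meta$p, method = "spearman"), 0.9)
})

test_that("niche sampler concentrates narrow-tolerance taxa and respects limits", {
  meta <- simulate_metacommunity(20, 0, 1, seed = 3)
  env <- seq(-2, 2, length.out = 18)

  # sigma -> Inf for all: reduces to a multinomial draw from p
  cfg_wide <- niche_sim_config(env, optima = rep(0, 20), tolerances = rep(1e6, 20),
                               depth = 2e5, seed = 5)
  counts <- simulate_niche_sample(meta, cfg_wide, 1)
  expect_gt(cor(counts / sum(counts), meta$p), 0.999)

  # a sigma = 0.01 taxon whose optimum matches exactly one sample env gets
  # >= 95% of its expected weight in that sample (direct evaluation of w)
  tol <- rep(1e6, 20); tol[4] <- 0.01
  opt <- rep(0, 20); opt[4] <- env[7]
  cfg_narrow <- niche_sim_config(env, opt, tol, depth = 1e4, seed = 5)
  w_focal <- vapply(seq_along(env), function(j) {
    w <- meta$p * exp(-(env[j] - opt)^2 / (2 * tol^2))
    (w / sum(w))[4]
  }, numeric(1))
  expect_gt(w_focal[7] / sum(w_focal), 0.95)

  # two taxa with identical optima and tolerance keep their p ratio
  tol2 <- rep(0.5, 20); opt2 <- rep(0, 20)
  cfg2 <- niche_sim_config(env, opt2, tol2, depth = 1e4)
  w <- assemblage:::niche_weights(meta$p, cfg2, 9)
  expect_equal(unname(w[1] / w[2]), unname(meta$p[1] / meta$p[2]))
})

test_that("simulate_dataset is reproducible, depth-exact, and plants breadth order", {
  s1 <- simulate_dataset(S = 60, groups = c(A = 4, B = 4), lambda = 0.5,
                         guild_plan = list(n_generalist = 5, n_specialist = 5),
                         depth = 2000, seed = 99, N = 200, burn_in_steps = 1000)
  s2 <- simulate_dataset(S = 60, groups = c(A = 4, B = 4), lambda = 0.5,
                         guild_plan = list(n_generalist = 5, n_specialist = 5),
                         depth = 2000, seed = 99, N = 200, burn_in_steps = 1000)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_equal(unname(colSums(s1$table$counts)), rep(2000, 8))
  expect_error(
    simulate_dataset(S = 5, guild_plan = list(n_generalist = 4, n_specialist = 4),
                     seed = 1),
    "exceeds"
  )

  # planted narrow-niche taxa have smaller mean Levins breadth than wide ones
  for (s in 1:5) {
    sim <- simulate_dataset(S = 100, groups = c(G = 12), lambda = 1,
                            guild_plan = list(n_generalist = 8, n_specialist = 8),
                            depth = 5000, seed = s)
    b <- assemblage:::breadth_by_row(sim$table$counts)
    expect_lt(mean(b[sim$truth$guild == "specialist"], na.rm = TRUE),
              mean(b[sim$truth$guild == "generalist"], na.rm = TRUE))
  }
})

test_that("inject_correlated_pair plants rank-perfect pairs and preserves marginals", {
  set.seed(17)
  mat <- t(replicate(10, sample.int(500, 18)))  # tie-free rows
  tab <- make_table(mat, rep("G", 18))
  pos <- inject_correlated_pair(tab, "OTU01", "OTU02", "+", 1, seed = 2)
  expect_identical(rank(pos$counts["OTU01", ]), rank(pos$counts["OTU02", ]))
  neg <- inject_correlated_pair(tab, "OTU01", "OTU02", "-", 1, seed = 2)
  expect_identical(rank(neg$counts["OTU01", ]),
                   19 - rank(neg$counts["OTU02", ]))
  # marginal multisets (hence totals and alpha diversity inputs) preserved
  expect_identical(unname(sort(pos$counts["OTU01", ])),
                   unname(sort(tab$counts["OTU01", ])))
  expect_identical(unname(sort(pos$counts["OTU02", ])),
                   unname(sort(tab$counts["OTU02", ])))
  expect_identical(pos$counts["OTU03", ], tab$counts["OTU03", ])
  expect_error(inject_correlated_pair(tab, "OTU01", "nope", "+", 1), "unknown OTU")
})
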