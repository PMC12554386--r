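test_that("occurrence_frequency counts presence per sample", {
  m <- matrix(0, 3, 18); m[1, 1:9] <- 2; m[2, ] <- 1; m[3, 1] <- 0; m[3, 2] <- 5
  tab <- make_table(m, rep("G", 18))
  f <- occurrence_frequency(tab)
  expect_equal(unname(f), c(0.5, 1, 1 / 18))
})

test_that("predicted_frequency matches quadrature and obeys limits/monotonicity", {
  # quadrature oracle over a (p, Nm, d) grid, agreement to 1e-8
  grid <- expand.grid(p = c(0.001, 0.01, 0.05, 0.2, 0.5),
                      Nm = c(5, 20, 100, 1000),
                      d = c(1e-4, 1e-3, 1e-2))
  for (i in seq_len(nrow(grid))) {
    got <- predicted_frequency(grid$p[i], grid$Nm[i], grid$d[i])
    want <- occurrence_prob_quadrature(grid$p[i], grid$Nm[i], grid$d[i])
    expect_equal(got, want, tolerance = 1e-8)
  }

  # worked case from the model definition
  expect_equal(predicted_frequency(0.01, 100, 0.001),
               occurrence_prob_quadrature(0.01, 100, 0.001), tolerance = 1e-8)

  # vanishing drift: p >> d, Nm -> large pushes f to 1
  expect_gt(predicted_frequency(0.1, 1e6, 1e-3), 1 - 1e-9)
  # interiority at p = d
  f_at_d <- predicted_frequency(0.01, 200, 0.01)
  expect_gt(f_at_d, 0); expect_lt(f_at_d, 1)

  # monotone in p (fixed Nm, d) and in Nm (p > d); strict away from the
  # floating-point saturation at 1, non-strict globally
  ps <- seq(0.001, 0.5, length.out = 40)
  f_p <- predicted_frequency(ps, 50, 1e-3)
  expect_true(all(diff(f_p) >= 0))
  interior <- f_p < 1 - 1e-12
  expect_true(all(diff(f_p[interior]) > 0))
  nms <- 10^seq(0, 4, length.out = 30)
  f_nm <- vapply(nms, function(nm) predicted_frequency(0.05, nm, 1e-3), numeric(1))
  expect_true(all(diff(f_nm) >= 0))
  expect_true(all(diff(f_nm[f_nm < 1 - 1e-12]) > 0))

  expect_error(predicted_frequency(0, 10, 1e-3), "p must")
  expect_error(predicted_frequency(0.1, -1, 1e-3), "Nm must")
  expect_error(predicted_frequency(0.1, 10, 2), "d must")
})

test_that("fit is self-consistent on exact model frequencies", {
  set.seed(2)
  p <- sort(rlnorm(80, -6, 1.5)); p <- p / sum(p) * 0.9
  d <- 1e-4
  f_exact <- predicted_frequency(p, 50, d)
  fit <- assemblage:::fit_nm_core(p, f_exact, d)
  expect_equal(fit$Nm, 50, tolerance = 1e-3 / 50)
  sst <- sum((f_exact - mean(f_exact))^2)
  expect_equal(1 - fit$sse / sst, 1, tolerance = 1e-6)
})

test_that("fit_ncm recovers immigration from neutral simulations", {
  # scaled-down version of the full harness in test-acceptance.R: one seed
  meta <- simulate_metacommunity(300, 0, 1.5, seed = 1)
  set.seed(1)
  counts <- sapply(1:30, function(j) {
    f <- assemblage:::neutral_local_freq(meta$p, 1000, 0.1, 10000)
    as.vector(rmultinom(1, 10000, f))
  })
  rownames(counts) <- names(meta$p); colnames(counts) <- paste0("S", 1:30)
  tab <- make_table(counts, rep("G", 30))
  # detection limit of the generative process: half an individual out of N
  fit <- fit_ncm(tab, d = 1 / (2 * 1000))
  expect_gt(fit$Nm, 70); expect_lt(fit$Nm, 130)
  expect_gt(fit$r_squared, 0.5)
  expect_equal(fit$m, fit$Nm / fit$N)

  # Nm invariant to duplicating every sample
  dup <- cbind(counts, counts)
  colnames(dup) <- paste0("S", 1:60)
  fit2 <- fit_ncm(make_table(dup, rep("G", 60)), d = 1 / 2000)
  expect_equal(fit2$Nm, fit$Nm, tolerance = 1e-6)

  # partition is consistent with the Wilson band
  above <- fit$taxa$partition == "above"
  expect_true(all(fit$taxa$f_obs[above] > fit$taxa$ci_high[above]))
  within <- fit$taxa$partition == "within"
  expect_true(all(fit$taxa$f_obs[within] >= fit$taxa$ci_low[within] &
                  fit$taxa$f_obs[within] <= fit$taxa$ci_high[within]))
})

test_that("fit_ncm refuses degenerate inputs", {
  m <- matrix(3, 6, 6)  # every taxon everywhere: all f_obs = 1
  expect_error(fit_ncm(make_table(m, rep("G", 6))), "SST = 0")
})

test_that("niche filtering degrades the neutral fit relative to neutral data", {
  for (s in 1:3) {
    neutral <- simulate_dataset(S = 150, groups = c(G = 15), lambda = 0,
                                depth = 5000, seed = s, N = 500,
                                burn_in_steps = 5000)
    niche <- simulate_dataset(S = 150, groups = c(G = 15), lambda = 1,
                              depth = 5000, seed = s)
    r2_neutral <- fit_ncm(neutral$table, d = 1 / 1000)$r_squared
    r2_niche <- fit_ncm(niche$table, d = 1 / 1000)$r_squared
    expect_gt(r2_neutral, r2_niche)
  }
})

test_that("guild/group strata are fitted or skipped with reasons", {
  sim <- simulate_dataset(S = 150, groups = c(A = 6, B = 6, C = 6), lambda = 0.6,
                          guild_plan = list(n_generalist = 12, n_specialist = 12),
                          depth = 5000, seed = 5, N = 300, burn_in_steps = 3000)
  guilds <- classify_guilds(sim$table, n_perm = 150, seed = 5)
  out <- fit_ncm_by_guild_and_group(sim$table, guilds)
  expect_true(length(out$fits) + length(out$skipped) == 6L)
  for (f in out$fits) expect_s3_class(f, "ncm_fit")

  # all-non_significant guilds: every stratum skipped with a diagnostic
  empty <- guilds
  empty$guild <- "non_significant"
  expect_message(out2 <- fit_ncm_by_guild_and_group(sim$table, empty),
                 "all strata skipped")
  expect_length(out2$fits, 0L)
  expect_true(all(grepl("no OTUs classified", out2$skipped)))

  # a 3-sample group is skipped with a named reason
  tiny <- subset_table(sim$table,
                       samples = c(names(sim$table$groups)[sim$table$groups == "A"][1:3],
                                   names(sim$table$groups)[sim$table$groups == "B"]))
  out3 <- fit_ncm_by_guild_and_group(tiny, guilds)
  expect_match(out3$skipped[["A|generalist"]], "3 samples")
})
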