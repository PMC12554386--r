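# Seeded synthetic-community generators. These are first-class, tested code:
# the study's sequencing data is unavailable, so every downstream stage is
# validated on tables with planted ground truth (known immigration rate,
# planted guilds, planted correlations).

#' Simulate a lognormal metacommunity
#'
#' Draws `S` lognormal abundances (rank-abundance curve) and normalizes them
#' to a relative-abundance vector, sorted descending. `sigma_log = 0` gives
#' the uniform metacommunity `1/S`.
#'
#' @param S Number of taxa (>= 2).
#' @param mu_log,sigma_log Mean and standard deviation of log abundance.
#' @param seed Integer seed (optional; when `NULL` the current RNG stream is used).
#' @return Object of class `metacommunity`: list with `p` (named, sums to 1)
#'   and the generating parameters.
#' @export
simulate_metacommunity <- function(S, mu_log = 0, sigma_log = 1.5, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || S < 2) abort_arg("S must be a single integer >= 2")
  if (sigma_log < 0) abort_arg("sigma_log must be >= 0")
  S <- as.integer(S)
  p <- with_seed(seed, {
    x <- stats::rlnorm(S, meanlog = mu_log, sdlog = sigma_log)
    sort(x / sum(x), decreasing = TRUE)
  })
  names(p) <- sprintf("OTU%04d", seq_len(S))
  structure(list(p = p, S = S, mu_log = mu_log, sigma_log = sigma_log),
            class = "metacommunity")
}

#' Neutral simulation configuration
#'
#' @param S Taxa count (taken from the metacommunity when omitted).
#' @param N Local community size in individuals (>= 10).
#' @param m Immigration probability per death, in `[0, 1]`.
#' @param burn_in_steps Moran steps before reading the community
#'   (default `10 * N`, empirically sufficient for drift equilibrium at
#'   `N <= 1e4` when initialized from the metacommunity).
#' @param n_samples Number of local communities to simulate.
#' @param depth Reads per sample (>= 100).
#' @param seed Integer seed.
#' @return A `neutral_sim_config` list.
#' @export
neutral_sim_config <- function(S = NULL, N = 1000, m = 0.1, burn_in_steps = 10 * N,
                               n_samples = 1L, depth = 10000, seed = NULL) {
  if (m < 0 || m > 1) abort_arg("m must be in [0, 1]")
  if (N < 10) abort_arg("N must be >= 10")
  if (depth < 100) abort_arg("depth must be >= 100")
  structure(list(S = S, N = as.integer(N), m = m,
                 burn_in_steps = as.integer(burn_in_steps),
                 n_samples = as.integer(n_samples),
                 depth = as.integer(depth), seed = seed),
            class = "neutral_sim_config")
}

# One Moran run: N individuals initialized by a multinomial draw from p; each
# step a uniformly chosen individual dies and is replaced by an immigrant
# drawn from p with probability m, otherwise by a copy of a uniformly chosen
# surviving local individual. Returns local relative abundances (length S).
neutral_local_freq <- function(p, N, m, burn_in_steps) {
  S <- length(p)
  comm <- sample.int(S, N, replace = TRUE, prob = p)
  steps <- as.integer(burn_in_steps)
  if (steps > 0L) {
    imm <- stats::runif(steps) < m
    death <- sample.int(N, steps, replace = TRUE)
    copy_raw <- sample.int(N - 1L, steps, replace = TRUE)
    n_imm <- sum(imm)
    imm_pool <- if (n_imm > 0L) sample.int(S, n_imm, replace = TRUE, prob = p) else integer(0)
    k <- 0L
    for (t in seq_len(steps)) {
      i <- death[t]
      if (imm[t]) {
        k <- k + 1L
        comm[i] <- imm_pool[k]
      } else {
        j <- copy_raw[t]
        if (j >= i) j <- j + 1L
        comm[i] <- comm[j]
      }
    }
  }
  tabulate(comm, nbins = S) / N
}

#' Simulate one neutral local-community sample
#'
#' Moran-type overlapping-generation dynamics under immigration from the
#' metacommunity, followed by multinomial read sampling at the configured
#' depth. The returned counts sum exactly to `depth`.
#'
#' @param meta A [simulate_metacommunity()] object.
#' @param cfg A [neutral_sim_config()].
#' @return Named integer vector of length `S` summing to `cfg$depth`.
#' @export
simulate_neutral_sample <- function(meta, cfg) {
  stopifnot(inherits(meta, "metacommunity"), inherits(cfg, "neutral_sim_config"))
  with_seed(cfg$seed, {
    freq <- neutral_local_freq(meta$p, cfg$N, cfg$m, cfg$burn_in_steps)
    counts <- as.vector(stats::rmultinom(1L, cfg$depth, freq))
    names(counts) <- names(meta$p)
    counts
  })
}

#' Niche simulation configuration
#'
#' Gaussian environmental responses: taxon k's expected weight in sample j is
#' `p_k * exp(-(env_j - optimum_k)^2 / (2 * tolerance_k^2))`. Wide tolerances
#' produce habitat generalists, narrow ones specialists.
#'
#' @param env Per-sample environmental value (finite scalar per sample).
#' @param optima Per-taxon niche optimum.
#' @param tolerances Per-taxon niche width (> 0).
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return A `niche_sim_config` list.
#' @export
niche_sim_config <- function(env, optima, tolerances, depth = 10000, seed = NULL) {
  if (any(!is.finite(env))) abort_arg("env must be finite")
  if (any(tolerances <= 0)) abort_arg("tolerances must be > 0")
  if (length(optima) != length(tolerances)) abort_arg("optima and tolerances must have equal length")
  structure(list(env = env, optima = optima, tolerances = tolerances,
                 depth = as.integer(depth), seed = seed),
            class = "niche_sim_config")
}

niche_weights <- function(p, cfg, sample_index) {
  e <- cfg$env[sample_index]
  w <- p * exp(-(e - cfg$optima)^2 / (2 * cfg$tolerances^2))
  if (all(w == 0)) {
    abort_arg("all niche weights are zero in sample %d (pathological optima)", sample_index)
  }
  w / sum(w)
}

#' Simulate one niche-filtered sample
#'
#' @param meta A [simulate_metacommunity()] object.
#' @param cfg A [niche_sim_config()]; `optima`/`tolerances` must match `meta$S`.
#' @param sample_index Which entry of `cfg$env` to use.
#' @return Named integer count vector summing to `cfg$depth`.
#' @export
simulate_niche_sample <- function(meta, cfg, sample_index) {
  stopifnot(inherits(meta, "metacommunity"), inherits(cfg, "niche_sim_config"))
  if (length(cfg$optima) != meta$S) abort_arg("config has %d taxa, metacommunity %d",
                                              length(cfg$optima), meta$S)
  with_seed(cfg$seed, {
    w <- niche_weights(meta$p, cfg, sample_index)
    counts <- as.vector(stats::rmultinom(1L, cfg$depth, w))
    names(counts) <- names(meta$p)
    counts
  })
}

#' Simulate a multi-group dataset with planted assembly process and guilds
#'
#' Each sample's expected composition is the convex combination
#' `(1 - lambda) * neutral + lambda * niche` of a Moran neutral stationary
#' draw and Gaussian niche-filtered weights, sampled multinomially at `depth`
#' (so the multinomial noise model is uniform across `lambda`).
#' `lambda = 0` is pure neutral assembly, `lambda = 1` pure environmental
#' filtering. Planted wide-tolerance taxa are the ground-truth generalists,
#' narrow-tolerance taxa the specialists; remaining taxa get an intermediate
#' niche width. Samples sit on an environmental gradient spanning
#' `[-env_spread, env_spread]`, assigned to groups in blocks so each group is
#' an environmental window (group-level determinism under filtering).
#'
#' @param S Number of taxa.
#' @param groups Named integer vector: samples per group, e.g.
#'   `c(SA = 6, PUR = 6, OF = 6)`.
#' @param lambda Process mix in `[0, 1]`.
#' @param guild_plan List with `n_generalist` and `n_specialist` counts.
#' @param depth Reads per sample.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param m,N Immigration rate and local community size of the neutral
#'   component.
#' @param mu_log,sigma_log Metacommunity lognormal parameters.
#' @param env Optional per-sample environment (default: even gradient).
#' @param env_spread Half-width of the default gradient.
#' @param sigma_wide,sigma_narrow,sigma_background Niche widths of planted
#'   generalists, planted specialists, and background taxa (same units as
#'   `env`).
#' @param burn_in_steps Moran burn-in (default `10 * N`).
#' @return List with `table` (a [community_table()]) and `truth` (class
#'   `synthetic_truth`: per-taxon guild labels, niche parameters, and the
#'   dataset-level `lambda`, `m`, `N`).
#' @export
simulate_dataset <- function(S = 300, groups = c(SA = 6, PUR = 6, OF = 6),
                             lambda = 0.5,
                             guild_plan = list(n_generalist = 15, n_specialist = 15),
                             depth = 10000, seed = 1L,
                             m = 0.1, N = 1000,
                             mu_log = 0, sigma_log = 1.5,
                             env = NULL, env_spread = 2,
                             sigma_wide = 10, sigma_narrow = 0.08,
                             sigma_background = 0.8,
                             burn_in_steps = 10 * N) {
  if (lambda < 0 || lambda > 1) abort_arg("lambda must be in [0, 1]")
  n_gen <- as.integer(guild_plan$n_generalist)
  n_spec <- as.integer(guild_plan$n_specialist)
  if (n_gen + n_spec > S) abort_arg("guild_plan (%d + %d) exceeds S = %d", n_gen, n_spec, S)
  if (is.null(names(groups)) || any(groups < 1)) {
    abort_arg("`groups` must be a named vector of positive sample counts")
  }
  n_samples <- sum(groups)
  sample_groups <- rep(names(groups), times = groups)
  sids <- sprintf("%s_%02d", sample_groups, unlist(lapply(groups, seq_len)))
  if (is.null(env)) {
    env <- if (n_samples == 1L) 0 else seq(-env_spread, env_spread, length.out = n_samples)
  }
  if (length(env) != n_samples) abort_arg("env must have one value per sample")

  with_seed(seed, {
    meta <- simulate_metacommunity(S, mu_log, sigma_log, seed = NULL)
    guild <- rep("intermediate", S)
    planted <- sample.int(S, n_gen + n_spec)
    guild[planted[seq_len(n_gen)]] <- "generalist"
    guild[planted[n_gen + seq_len(n_spec)]] <- "specialist"
    tolerances <- rep(sigma_background, S)
    tolerances[guild == "generalist"] <- sigma_wide
    tolerances[guild == "specialist"] <- sigma_narrow
    # Specialist optima sit on actual sample environments so each specialist
    # has at least one matching habitat; others roam the gradient freely.
    optima <- stats::runif(S, min(env) - 0.5, max(env) + 0.5)
    optima[guild == "specialist"] <- sample(env, sum(guild == "specialist"), replace = TRUE)
    ncfg <- niche_sim_config(env, optima, tolerances, depth = depth)

    counts <- matrix(0L, S, n_samples, dimnames = list(names(meta$p), sids))
    for (j in seq_len(n_samples)) {
      w_neutral <- if (lambda < 1) neutral_local_freq(meta$p, N, m, burn_in_steps) else 0
      w_niche <- if (lambda > 0) niche_weights(meta$p, ncfg, j) else 0
      w <- (1 - lambda) * w_neutral + lambda * w_niche
      counts[, j] <- as.vector(stats::rmultinom(1L, depth, w))
    }
    table <- community_table(counts, stats::setNames(sample_groups, sids))
    truth <- structure(
      data.frame(otu_id = names(meta$p), guild = guild,
                 optimum = optima, tolerance = tolerances,
                 p_meta = unname(meta$p), stringsAsFactors = FALSE),
      class = c("synthetic_truth", "data.frame"))
    attr(truth, "lambda") <- lambda
    attr(truth, "m") <- m
    attr(truth, "N") <- N
    attr(truth, "seed") <- seed
    attr(truth, "env") <- stats::setNames(env, sids)
    list(table = table, truth = truth)
  })
}

#' Plant a correlated OTU pair by copula resampling
#'
#' Replaces the two rows with draws from a Gaussian copula of correlation
#' `+strength` or `-strength`, mapped back to each row's original value
#' multiset (the ranks follow the copula; the marginal abundance
#' distributions — and hence totals and diversity statistics — are
#' preserved). `strength = 1` makes the rows comonotone (`sign = "+"`) or
#' antitone (`sign = "-"`).
#'
#' @param table A `community_table`.
#' @param otu_a,otu_b OTU ids.
#' @param sign `"+"` or `"-"`.
#' @param strength Correlation magnitude in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `community_table` with the two rows resampled.
#' @export
inject_correlated_pair <- function(table, otu_a, otu_b, sign = c("+", "-"),
                                   strength = 0.9, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  sign <- match.arg(sign)
  if (strength <= 0 || strength > 1) abort_arg("strength must be in (0, 1]")
  missing_ids <- setdiff(c(otu_a, otu_b), rownames(table$counts))
  if (length(missing_ids)) abort_arg("unknown OTU id(s): %s", paste(missing_ids, collapse = ", "))
  n <- ncol(table$counts)
  rho <- if (sign == "+") strength else -strength
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    counts <- table$counts
    # rank-map latent draws onto each row's original sorted values
    counts[otu_a, ] <- sort(counts[otu_a, ])[rank(z1, ties.method = "first")]
    counts[otu_b, ] <- sort(counts[otu_b, ])[rank(z2, ties.method = "first")]
    community_table(counts, table$groups)
  })
}
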