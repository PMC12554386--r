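# Sloan neutral community model: occurrence frequency vs. metacommunity
# relative abundance, fitted by least squares over the immigration parameter
# Nm, with Wilson prediction bands and an above/within/below partition.

#' Observed occurrence frequency per taxon
#'
#' Fraction of samples in which each OTU has a nonzero count.
#'
#' @param table A `community_table`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
occurrence_frequency <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (ncol(table$counts) < 2L) abort_arg("need >= 2 samples")
  rowMeans(table$counts > 0)
}

#' Neutral-model predicted occurrence frequency
#'
#' Under Sloan's neutral model a taxon with metacommunity relative abundance
#' `p` is detected (local relative abundance above the detection limit `d`)
#' with probability `1 - I_d(Nm * p, Nm * (1 - p))`, where `I` is the
#' regularized incomplete beta function. Vectorized over `p`.
#'
#' @param p Metacommunity relative abundance, in `(0, 1)`.
#' @param Nm Immigration parameter (metacommunity size x immigration rate), > 0.
#' @param d Detection limit as a relative abundance, in `(0, 1)`.
#' @return Predicted frequency in `[0, 1]`.
#' @export
predicted_frequency <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) abort_arg("p must lie in (0, 1)")
  if (length(Nm) != 1L || Nm <= 0) abort_arg("Nm must be a single value > 0")
  if (length(d) != 1L || d <= 0 || d >= 1) abort_arg("d must lie in (0, 1)")
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

#' Fit the neutral community model
#'
#' Estimates `Nm` by minimizing the sum of squared deviations between
#' observed occurrence frequencies and [predicted_frequency()] over
#' `Nm in (0, Nm_max]`, seeding a bounded golden-section search
#' (`stats::optimize`, relative tolerance 1e-6) from a log-spaced grid.
#' `R^2 = 1 - SSE/SST` is reported unclamped (it may be negative).
#' Per-taxon 95% Wilson score intervals around the predicted frequency
#' (effective trials = number of samples) define the `above` / `within` /
#' `below` partition.
#'
#' Taxa with zero occurrence are excluded before fitting. `p` is the mean of
#' per-sample relative abundances (robust to library-size variation).
#'
#' @param table A `community_table`.
#' @param d Detection limit; default `1 / mean(library size)` (the smallest
#'   observable relative abundance).
#' @param N Community size used to convert `Nm` to the migration rate
#'   `m = Nm / N`; default mean library size.
#' @param Nm_max Upper search bound for `Nm`.
#' @return Object of class `ncm_fit`: list with `Nm`, `m`, `N`, `d`,
#'   `r_squared`, `n_samples`, and `taxa` (data frame `otu_id`, `p`, `f_obs`,
#'   `f_pred`, `ci_low`, `ci_high`, `partition`).
#' @export
fit_ncm <- function(table, d = NULL, N = NULL, Nm_max = 1e7) {
  stopifnot(inherits(table, "community_table"))
  mean_lib <- mean(colSums(table$counts))
  if (is.null(d)) d <- 1 / mean_lib
  if (is.null(N)) N <- mean_lib
  if (d <= 0 || d >= 1) abort_arg("d must lie in (0, 1)")

  f_obs <- occurrence_frequency(table)
  rel <- to_relative_abundance(table, "per_sample")$proportions
  p <- rowMeans(rel)
  keep <- f_obs > 0 & p > 0 & p < 1
  f_obs <- f_obs[keep]
  p <- p[keep]
  if (length(p) < 5L) abort_arg("need >= 5 taxa with nonzero occurrence to fit")
  sst <- sum((f_obs - mean(f_obs))^2)
  if (sst == 0) {
    abort_arg("all observed occurrence frequencies identical (SST = 0): R^2 undefined, fit refused")
  }

  fit <- fit_nm_core(p, f_obs, d, Nm_max)
  Nm <- fit$Nm
  r_squared <- 1 - fit$sse / sst

  f_pred <- predicted_frequency(p, Nm, d)
  ci <- wilson_interval(f_pred, ncol(table$counts))
  partition <- ifelse(f_obs > ci$high, "above", ifelse(f_obs < ci$low, "below", "within"))
  taxa <- data.frame(otu_id = names(f_obs), p = unname(p), f_obs = unname(f_obs),
                     f_pred = unname(f_pred), ci_low = unname(ci$low),
                     ci_high = unname(ci$high), partition = unname(partition),
                     stringsAsFactors = FALSE)
  structure(list(Nm = Nm, N = N, m = Nm / N, d = d, r_squared = r_squared,
                 n_samples = ncol(table$counts), n_taxa = nrow(taxa), taxa = taxa),
            class = "ncm_fit")
}

# Least-squares estimation of Nm: log-spaced grid seed, then bounded
# golden-section refinement (objective is smooth but flat at large Nm).
fit_nm_core <- function(p, f_obs, d, Nm_max = 1e7) {
  sse_at <- function(nm) sum((f_obs - predicted_frequency(p, nm, d))^2)
  grid <- 10^seq(-2, log10(Nm_max), length.out = 120)
  sses <- vapply(grid, sse_at, numeric(1L))
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse_at, interval = c(lo, hi), tol = lo * 1e-8)
  # polish around the optimum to reach tight self-consistency
  opt2 <- stats::optimize(sse_at, interval = c(opt$minimum * 0.9, opt$minimum * 1.1),
                          tol = opt$minimum * 1e-9)
  if (opt2$objective < opt$objective) opt <- opt2
  list(Nm = opt$minimum, sse = opt$objective)
}

# 95% Wilson score interval for a proportion phat with n effective trials.
wilson_interval <- function(phat, n, z = stats::qnorm(0.975)) {
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("ncm_fit: Nm = %.4g, m = %.4g (N = %.4g), R^2 = %.4f, d = %.3g, %d taxa / %d samples\n",
              x$Nm, x$m, x$N, x$r_squared, x$d, x$n_taxa, x$n_samples))
  invisible(x)
}

#' Fit the neutral model per (group, guild) stratum
#'
#' Restricts the table to each group's samples and each guild's OTUs,
#' re-normalizes within the stratum, and fits. Strata with fewer than 5
#' usable taxa or 4 samples are reported as skipped (with the reason), not
#' errors.
#'
#' @param table A `community_table`.
#' @param guilds A [classify_guilds()] result.
#' @param guild_labels Which guilds to stratify on.
#' @param ... Passed to [fit_ncm()].
#' @return List with `fits` (named `group|guild` -> `ncm_fit`) and `skipped`
#'   (named character reasons).
#' @export
fit_ncm_by_guild_and_group <- function(table, guilds,
                                       guild_labels = c("generalist", "specialist"),
                                       ...) {
  stopifnot(inherits(table, "community_table"), inherits(guilds, "guild_classification"))
  fits <- list()
  skipped <- character(0)
  for (g in unique(table$groups)) {
    g_samples <- names(table$groups)[table$groups == g]
    for (lab in guild_labels) {
      key <- paste(g, lab, sep = "|")
      members <- guild_members(guilds, lab)
      if (length(members) == 0L) {
        skipped[key] <- sprintf("no OTUs classified as %s", lab)
        next
      }
      if (length(g_samples) < 4L) {
        skipped[key] <- sprintf("only %d samples in group %s (need >= 4)", length(g_samples), g)
        next
      }
      sub <- tryCatch(subset_table(table, samples = g_samples, otus = members),
                      error = function(e) NULL)
      if (is.null(sub) || nrow(sub$counts) < 5L) {
        skipped[key] <- sprintf("fewer than 5 %s OTUs present in group %s", lab, g)
        next
      }
      fit <- tryCatch(fit_ncm(sub, ...), error = function(e) conditionMessage(e))
      if (is.character(fit)) skipped[key] <- fit else fits[[key]] <- fit
    }
  }
  if (length(fits) == 0L && length(skipped) > 0L) {
    message("fit_ncm_by_guild_and_group: all strata skipped (",
            paste(unique(skipped), collapse = "; "), ")")
  }
  list(fits = fits, skipped = skipped)
}
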