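# Normalized stochasticity ratio: observed pairwise dissimilarities compared
# to a null-model expectation under random community assembly.

#' Pairwise community dissimilarity
#'
#' Computed on per-sample relative abundances. Metrics: `ruzicka`
#' (abundance-based Jaccard, `1 - sum(min) / sum(max)`, the package default
#' for NST), `bray_curtis` (`sum|x - y| / sum(x + y)`), `jaccard_binary`
#' (on presence/absence).
#'
#' @param table A `community_table` (typically restricted to one group).
#' @param metric One of `"ruzicka"`, `"bray_curtis"`, `"jaccard_binary"`.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
pairwise_dissimilarity <- function(table, metric = c("ruzicka", "bray_curtis",
                                                     "jaccard_binary")) {
  stopifnot(inherits(table, "community_table"))
  metric <- match.arg(metric)
  if (ncol(table$counts) < 2L) abort_arg("need >= 2 samples")
  x <- to_relative_abundance(table, "per_sample")$proportions
  dissim_matrix(x, metric)
}

dissim_matrix <- function(x, metric) {
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- x[, i]; b <- x[, j]
      dij <- switch(metric,
        ruzicka = 1 - sum(pmin(a, b)) / sum(pmax(a, b)),
        bray_curtis = sum(abs(a - b)) / sum(a + b),
        jaccard_binary = {
          pa <- a > 0; pb <- b > 0
          1 - sum(pa & pb) / sum(pa | pb)
        })
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Null-model randomization of a community table
#'
#' Each sample keeps its observed richness (number of nonzero taxa) and its
#' nonzero count multiset; taxon identities are redrawn from the regional
#' pool (taxa present somewhere in the table):
#' \describe{
#'   \item{`proportional_fix`}{identities drawn without replacement with
#'     probability proportional to regional occurrence frequency.}
#'   \item{`occurrence_fix`}{identities drawn uniformly from the pool.}
#' }
#' Abundances are assigned by randomly permuting the sample's original
#' nonzero counts over the drawn taxa.
#'
#' @param table A `community_table`.
#' @param algorithm `"proportional_fix"` or `"occurrence_fix"`.
#' @param seed Integer seed.
#' @return A `community_table` of the same dimensions.
#' @export
randomize_community <- function(table, algorithm = c("proportional_fix", "occurrence_fix"),
                                seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  algorithm <- match.arg(algorithm)
  counts <- table$counts
  pool <- which(rowSums(counts) > 0)
  occ <- rowMeans(counts[pool, , drop = FALSE] > 0)
  with_seed(seed, {
    out <- randomize_counts(counts, pool, occ, algorithm)
    community_table(out, table$groups)
  })
}

# Core randomizer without validation/seed plumbing; used in the NST loop.
randomize_counts <- function(counts, pool, occ, algorithm) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    nz <- counts[, j] > 0
    rich <- sum(nz)
    if (rich == 0L) abort_arg("sample '%s' has zero richness", colnames(counts)[j])
    prob <- if (algorithm == "proportional_fix") occ else NULL
    taxa <- if (rich == length(pool)) pool else pool[sample.int(length(pool), rich, prob = prob)]
    vals <- counts[nz, j]
    out[taxa, j] <- if (rich > 1L) sample(vals) else vals
  }
  out
}

#' Normalized stochasticity ratio of a group
#'
#' For each sample pair, the observed dissimilarity `d_obs` is compared with
#' the mean dissimilarity `e_null` over `n_reps` null-model randomizations:
#' `nst_ij = d_obs / e_null` when `d_obs <= e_null`, else
#' `(1 - d_obs) / (1 - e_null)`. Both branches map to `[0, 1]`; observed
#' matching the null gives 1, deterministic extremes (`d_obs` at 0 or 1 while
#' the null is interior) give 0. If `e_null` is exactly 0 or 1 the pair gets
#' 1 when `d_obs` equals it and 0 otherwise. The group value is the
#' unweighted mean over pairs; values above 0.5 are read as stochastic
#' dominance.
#'
#' @param table A `community_table` restricted to one group (>= 3 samples).
#' @param metric Dissimilarity metric, see [pairwise_dissimilarity()].
#' @param algorithm Null model, see [randomize_community()].
#' @param n_reps Number of randomizations (>= 100).
#' @param seed Integer seed.
#' @param group Group label recorded in the result.
#' @return Object of class `nst_result`: list with `group`, `metric`,
#'   `null_algorithm`, `n_reps`, `seed`, `pairs` (data frame `sample_i`,
#'   `sample_j`, `d_obs`, `e_null`, `nst_ij`) and `nst_group`.
#' @export
compute_nst <- function(table, metric = c("ruzicka", "bray_curtis", "jaccard_binary"),
                        algorithm = c("proportional_fix", "occurrence_fix"),
                        n_reps = 1000, seed = NULL,
                        group = unique(table$groups)[1L]) {
  stopifnot(inherits(table, "community_table"))
  metric <- match.arg(metric)
  algorithm <- match.arg(algorithm)
  if (ncol(table$counts) < 3L) abort_arg("NST needs >= 3 samples in the group")
  if (n_reps < 100) abort_arg("n_reps must be >= 100")

  d_obs <- pairwise_dissimilarity(table, metric)
  n <- ncol(table$counts)
  counts <- table$counts
  pool <- which(rowSums(counts) > 0)
  occ <- rowMeans(counts[pool, , drop = FALSE] > 0)
  e_null <- with_seed(seed, {
    acc <- matrix(0, n, n)
    for (r in seq_len(n_reps)) {
      rnd <- randomize_counts(counts, pool, occ, algorithm)
      rnd <- sweep(rnd, 2L, colSums(rnd), "/")
      acc <- acc + dissim_matrix(rnd, metric)
    }
    acc / n_reps
  })

  idx <- which(upper.tri(d_obs), arr.ind = TRUE)
  dv <- d_obs[upper.tri(d_obs)]
  ev <- e_null[upper.tri(e_null)]
  nst_ij <- mapply(nst_pair, dv, ev)
  pairs <- data.frame(sample_i = colnames(counts)[idx[, 1L]],
                      sample_j = colnames(counts)[idx[, 2L]],
                      d_obs = dv, e_null = ev, nst_ij = nst_ij,
                      stringsAsFactors = FALSE)
  structure(list(group = group, metric = metric, null_algorithm = algorithm,
                 n_reps = n_reps, seed = seed, pairs = pairs,
                 nst_group = mean(nst_ij)),
            class = "nst_result")
}

# Two-branch symmetric ratio; boundary nulls handled by the equality rule.
nst_pair <- function(d_obs, e_null, tol = 1e-12) {
  if (e_null <= tol || e_null >= 1 - tol) {
    return(if (abs(d_obs - e_null) <= tol) 1 else 0)
  }
  if (d_obs <= e_null) d_obs / e_null else (1 - d_obs) / (1 - e_null)
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("nst_result [%s]: NST = %.3f (%s, %s null, %d reps, %d pairs)\n",
              x$group, x$nst_group, x$metric, x$null_algorithm, x$n_reps, nrow(x$pairs)))
  invisible(x)
}

#' NST per (group, guild) stratum
#'
#' Restricts the table to each group's samples and guild's OTUs (abundances
#' re-normalized within the stratum) and runs [compute_nst()]. Strata with
#' fewer than 3 samples or 5 present OTUs are reported as skipped.
#'
#' @inheritParams compute_nst
#' @param guilds A [classify_guilds()] result.
#' @param guild_labels Guilds to stratify on.
#' @return List with `results` (named `group|guild` -> `nst_result`) and
#'   `skipped` (named character reasons).
#' @export
compute_nst_by_guild_and_group <- function(table, guilds,
                                           guild_labels = c("generalist", "specialist"),
                                           metric = "ruzicka",
                                           algorithm = "proportional_fix",
                                           n_reps = 1000, seed = NULL) {
  stopifnot(inherits(table, "community_table"), inherits(guilds, "guild_classification"))
  results <- list()
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
      if (length(g_samples) < 3L) {
        skipped[key] <- sprintf("only %d samples in group %s (need >= 3)", length(g_samples), g)
        next
      }
      sub <- tryCatch(subset_table(table, samples = g_samples, otus = members),
                      error = function(e) NULL)
      if (is.null(sub) || nrow(sub$counts) < 5L) {
        skipped[key] <- sprintf("fewer than 5 %s OTUs present in group %s", lab, g)
        next
      }
      res <- tryCatch(
        compute_nst(sub, metric = metric, algorithm = algorithm,
                    n_reps = n_reps, group = g,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, key)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) skipped[key] <- res else results[[key]] <- res
    }
  }
  list(results = results, skipped = skipped)
}
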