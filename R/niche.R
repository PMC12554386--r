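# Levins' niche breadth and generalist/specialist classification against a
# permutation null.

#' Levins' niche breadth
#'
#' `B = 1 / sum_j P_j^2` for a taxon's proportional abundance across `r`
#' sites; the inverse Simpson concentration. `B = r` for a perfectly even
#' taxon, `B = 1` for a single-site taxon.
#'
#' @param row_proportions Non-negative vector summing to 1 (within 1e-9 of a
#'   tolerance; a raw count vector may be passed and is normalized after a
#'   positivity check).
#' @return The breadth `B` in `[1, r]`.
#' @export
#' @examples
#' levins_breadth(c(0.25, 0.25, 0.25, 0.25))  # 4
#' levins_breadth(c(1, 0, 0, 0))              # 1
levins_breadth <- function(row_proportions) {
  if (any(row_proportions < 0) || anyNA(row_proportions)) {
    abort_arg("proportions must be non-negative")
  }
  s <- sum(row_proportions)
  if (s == 0) abort_arg("zero abundance vector has no niche breadth")
  if (abs(s - 1) > 1e-9) row_proportions <- row_proportions / s
  1 / sum(row_proportions^2)
}

# Vectorized breadth over the rows of a count matrix; rows with zero total -> NA.
breadth_by_row <- function(counts) {
  totals <- rowSums(counts)
  prop <- counts / ifelse(totals > 0, totals, NA_real_)
  b <- 1 / rowSums(prop^2)
  b[totals == 0] <- NA_real_
  b
}

permute_counts <- function(counts, scheme) {
  switch(scheme,
    within_sample_shuffle = apply(counts, 2L, sample),
    row_shuffle = t(apply(counts, 1L, sample)),
    column_label_permute = counts[, sample.int(ncol(counts)), drop = FALSE],
    abort_arg("unknown permutation scheme '%s'", scheme)
  )
}

#' Null distribution of niche breadths under table randomization
#'
#' For each of `n_perm` permutations the count table is randomized and all
#' per-OTU breadths recomputed; the 2.5% and 97.5% empirical quantiles
#' (linear interpolation between order statistics, `stats::quantile` type 7)
#' of each OTU's null breadths form the null band.
#'
#' Schemes:
#' \describe{
#'   \item{`within_sample_shuffle`}{(default) independently permute each
#'     sample's counts across OTUs. Preserves library sizes and every
#'     sample's count multiset; the null asks how evenly a taxon would be
#'     spread were abundances assigned to taxa at random within each sample.}
#'   \item{`row_shuffle`}{independently permute each OTU's counts across
#'     samples. Note that Levins breadth on row-normalized proportions is a
#'     function of the row's value multiset only, so this null is degenerate
#'     (null = observed for every OTU); it is retained for sensitivity
#'     analysis and for its documented degeneracy.}
#'   \item{`column_label_permute`}{permute sample columns jointly; breadth
#'     is invariant, so the null is always degenerate. Retained for
#'     completeness.}
#' }
#'
#' @param table A `community_table`.
#' @param n_perm Number of permutations (>= 100; quantiles are unstable below).
#' @param scheme Randomization scheme, see Details.
#' @param seed Integer seed (results are deterministic given the seed).
#' @return Data frame with columns `otu_id`, `low_ci`, `upp_ci`.
#' @export
null_breadth_distribution <- function(table, n_perm = 1000,
                                      scheme = c("within_sample_shuffle",
                                                 "row_shuffle",
                                                 "column_label_permute"),
                                      seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  scheme <- match.arg(scheme)
  if (n_perm < 100) abort_arg("n_perm must be >= 100 (quantiles unstable)")
  counts <- table$counts
  n_otus <- nrow(counts)
  with_seed(seed, {
    nulls <- matrix(NA_real_, n_otus, n_perm)
    for (k in seq_len(n_perm)) {
      nulls[, k] <- breadth_by_row(permute_counts(counts, scheme))
    }
    qs <- t(apply(nulls, 1L, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE, names = FALSE, type = 7))
    data.frame(otu_id = rownames(counts), low_ci = qs[, 1L], upp_ci = qs[, 2L],
               stringsAsFactors = FALSE)
  })
}

#' Classify OTUs into generalists and specialists
#'
#' Computes each OTU's observed Levins breadth on its row-normalized
#' proportions and compares it to a permutation null band: strictly above the
#' 97.5% null quantile is a `generalist`, strictly below the 2.5% quantile a
#' `specialist`, anything else (including OTUs with a degenerate null band)
#' `non_significant`. Ties never produce a call.
#'
#' @inheritParams null_breadth_distribution
#' @return Object of class `guild_classification`: data frame with columns
#'   `otu_id`, `B_obs`, `low_ci`, `upp_ci`, `guild`; attributes `n_perm`,
#'   `r` (number of sites), `scheme`, `seed`.
#' @export
classify_guilds <- function(table, n_perm = 1000,
                            scheme = c("within_sample_shuffle", "row_shuffle",
                                       "column_label_permute"),
                            seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  scheme <- match.arg(scheme)
  if (ncol(table$counts) < 4L) {
    abort_arg("guild classification needs >= 4 samples (breadth meaningless below)")
  }
  b_obs <- breadth_by_row(table$counts)
  band <- null_breadth_distribution(table, n_perm = n_perm, scheme = scheme, seed = seed)
  eps <- 1e-9
  guild <- rep("non_significant", nrow(table$counts))
  degenerate <- abs(band$upp_ci - band$low_ci) < eps & abs(b_obs - band$low_ci) < eps
  guild[!degenerate & b_obs > band$upp_ci + eps] <- "generalist"
  guild[!degenerate & b_obs < band$low_ci - eps] <- "specialist"
  guild[is.na(b_obs)] <- "non_significant"
  out <- data.frame(otu_id = band$otu_id, B_obs = b_obs,
                    low_ci = band$low_ci, upp_ci = band$upp_ci,
                    guild = guild, stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("guild_classification", "data.frame"),
            n_perm = n_perm, r = ncol(table$counts), scheme = scheme, seed = seed)
}

#' @export
print.guild_classification <- function(x, ...) {
  tab <- table(factor(x$guild, levels = c("generalist", "specialist", "non_significant")))
  cat(sprintf("guild_classification: %d OTUs over r = %s samples (%d permutations, scheme %s)\n",
              nrow(x), attr(x, "r"), attr(x, "n_perm"), attr(x, "scheme")))
  cat(sprintf("  generalists: %d, specialists: %d, non-significant: %d\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' OTU ids carrying a given guild label
#' @param guilds A `guild_classification`.
#' @param label `"generalist"`, `"specialist"` or `"non_significant"`.
#' @return Character vector of OTU ids.
#' @export
guild_members <- function(guilds, label) {
  stopifnot(inherits(guilds, "guild_classification"))
  guilds$otu_id[guilds$guild == label]
}
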