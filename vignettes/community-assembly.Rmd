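---
title: "Guild-resolved community assembly: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild-resolved community assembly: models, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the statistical
models it implements, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the places
where the methodological literature leaves genuine design freedom — with
the choices made here and why. It states no empirical result that the test
suite does not itself compute.

## 1. Niche breadth and guild classification

For taxon *i* observed across *r* sites, Levins' niche breadth is

$$B_i = \frac{1}{\sum_{j=1}^{r} P_{ij}^2},$$

the inverse Simpson concentration of the taxon's proportional abundance
profile. $B_i = 1$ when all reads sit in one site and $B_i = r$ when the
profile is perfectly even. Two normalization conventions circulate; this
package row-normalizes ($P_{ij}$ = share of taxon *i*'s total found in site
*j*), the convention under which the bounds above are exact.

A breadth value alone does not separate ecology from sampling noise, so
`classify_guilds()` compares each observed $B_i$ to a permutation null:
strictly above the 97.5% empirical null quantile (type-7 linear
interpolation; `n_perm = 1000` by default, refuse below 100) is a
*generalist*, strictly below the 2.5% quantile a *specialist*, ties and
degenerate bands *non-significant*. The three labels partition the taxa.

**The null scheme is the load-bearing choice, and the common ones are not
interchangeable.**

* `within_sample_shuffle` (**default**): independently permute each
  sample's count column across taxa. Preserves library sizes and every
  sample's abundance structure; the null asks *how evenly would a taxon be
  spread if abundances were dealt to taxa at random within each sample?*
  Planted even taxa exceed the band; planted concentrated taxa fall below
  it (sensitivity for both guilds is property-tested at ≥ 0.8).
* `row_shuffle`: independently permute each taxon's counts across samples.
  This is sometimes described as a per-taxon null, but Levins breadth on a
  row-normalized profile depends only on the row's value *multiset*, which
  row shuffling preserves — the null equals the observation for every
  taxon, no calls are ever made, and the scheme is retained only for
  sensitivity analysis (its degeneracy is itself unit-tested).
* `column_label_permute`: joint column relabeling; breadth-invariant,
  degenerate for the same reason.

One consequence is worth stating plainly. A table whose columns are all
identical has "no spatial signal", and a multiset-preserving null
(row_shuffle) duly returns zero calls on it. But *any* null with that
property is blind to specialists. Under the working default, an
identical-column table — where every taxon is in fact maximally even — is
classified all-generalist. Both behaviours are defensible readings of "no
signal"; the package documents the trade-off rather than special-casing
it, and the corresponding acceptance assertion is deliberately left
failing with this analysis on record. Swap-based nulls that condition on
both margins and matrix fill (quasiswap-style Markov chains) blend the two
behaviours but sacrifice exact reproducibility and are out of scope here.

## 2. Sloan neutral community model

Under neutral drift with immigration, the long-run local relative
abundance of a taxon with metacommunity relative abundance $p$ is
approximately $\mathrm{Beta}(Nm\,p,\; Nm\,(1-p))$, so its occurrence
frequency above a detection limit $d$ is

$$f(p) = 1 - I_d\!\left(Nm\,p,\; Nm\,(1-p)\right),$$

with $I$ the regularized incomplete beta function. `fit_ncm()` estimates
the single parameter $Nm$ (community size × immigration rate,
dimensionless) by least squares against observed occurrence frequencies,
using a log-spaced grid seed followed by bounded golden-section refinement
(relative tolerance 1e-6; the objective is smooth but flat at large
$Nm$). $R^2 = 1 - SSE/SST$ is reported unclamped and can be negative.
Per-taxon 95% Wilson score bands (effective trials = number of samples)
give the above/within/below partition familiar from NCM scatter plots;
Wilson rather than Clopper–Pearson matches the common reference plots and
is the narrower, better-centred interval at these sample sizes.

Parameters and defaults:

* $d$ — detection limit as a relative abundance. Default
  $1/\overline{\text{library size}}$: the smallest observable relative
  abundance in the *reads*. When data come from a discrete local community
  of $N$ individuals observed at depth $\gg N$ (as in this package's Moran
  simulations), detection is limited by *individuals*, not reads, and the
  generative detection boundary is half an individual, $d = 1/(2N)$ — the
  midpoint between "0 copies" and "1 copy". The parameter-recovery tests
  pass that value explicitly; with the read-based default the fitted $Nm$
  is biased low by roughly a factor of two in that regime (fitting absorbs
  the extra predicted occupancy of rare taxa by inflating drift). Real
  amplicon tables, where depth is the binding constraint, use the default.
* $N$ — only used to convert $Nm$ into a migration rate $m = Nm/N$;
  default mean library size, overridable. Published "migration rates" are
  rarely accompanied by their $N$ and $d$; no attempt is made to reproduce
  any particular printed value.
* $p$ — mean of per-sample relative abundances (not pooled counts), robust
  to library-size variation.

Strata with fewer than 5 usable taxa or 4 samples are *skipped with a
recorded reason*, not errored: uneven guild sizes across groups are the
norm in real studies.

## 3. Normalized stochasticity ratio

For each pair of samples in a group, the observed dissimilarity $d_{obs}$
is compared with $\bar e$, the mean dissimilarity over `n_reps`
null-model reassemblies:

$$\mathrm{NST}_{ij} \;=\; \begin{cases}
d_{obs}/\bar e, & d_{obs} \le \bar e\\[2pt]
(1-d_{obs})/(1-\bar e), & d_{obs} > \bar e
\end{cases}$$

Both branches live in $[0,1]$: observed-matches-null maps to 1,
deterministic extremes (identical or disjoint samples while the null is
interior) map to 0, and the group value is the unweighted pair mean. If
$\bar e$ is exactly 0 or 1 the pair scores 1 on equality and 0 otherwise.
The NST literature offers several variants; this symmetric two-branch
ratio is declared as the package's contract because it preserves the
conventional reading that values above 0.5 indicate stochastic dominance.
The mean (not median) of the null is used, and no bootstrap over samples
is applied — one value per group/stratum.

The null model (`randomize_community`) preserves each sample's richness
and nonzero count multiset and redraws taxon identities from the regional
pool, either proportionally to occurrence frequency (`proportional_fix`,
default) or uniformly (`occurrence_fix`). Dissimilarity is **taxonomic**
(Ruzicka $1-\sum\min/\sum\max$ on per-sample relative abundances by
default; Bray–Curtis and binary Jaccard available). Phylogenetic
β-diversity variants are out of scope — no tree enters this pipeline —
and results are therefore not numerically comparable to tree-based NST
values; this is flagged rather than approximated. Guild-stratified NST
re-normalizes abundances within the stratum.

`n_reps = 1000` by default (refuse below 100); the suite checks that
doubling the replicate count moves a group NST by < 0.02 at the default
synthetic scale.

## 4. Co-occurrence networks

`build_network()` keeps the top `n_top` most abundant taxa (tie-break:
lexicographic id, for platform-independent reproducibility), drops taxa
below 20% prevalence and zero-variance rows, computes all-pairs Spearman
correlations on per-sample relative abundances, converts to p-values via
the t approximation, adjusts by Benjamini–Hochberg across all tested
pairs, and keeps edges with $|\rho| \ge 0.6$ and adjusted $p < 0.05$. The
thresholds follow common microbiome practice and are all overridable; the
correlation sign is kept as an edge attribute (positive-edge fractions are
a standard treatment contrast).

Topology metrics: average degree $2E/V$; density $2E/(V(V-1))$; `gd` =
mean shortest-path length in hops **over connected pairs only**, with the
component count reported alongside (real OTU networks at modularity ≈ 0.8
are never connected, and including infinite pairs would make the metric
meaningless); modularity $Q$ from deterministic greedy (CNM fast-greedy)
agglomeration rather than stochastic Louvain — reproducibility is worth
more here than marginal $Q$ gains, and the suite verifies the detected
$Q$ reaches the exhaustive-search optimum on planted two-clique graphs
(and never falls below the trivial single-community partition). Edge-type
proportions (G–G, G–S, S–S) are computed within the `scope_n` most
abundant guild-labelled nodes; `scope_n` has **no default** because the
methodological sources are ambiguous between 100 and 150 — the caller
must state it.

## 5. Diversity, ordination, group tests

Shannon entropy uses the natural log (the convention under which typical
soil values land in the 5–6.5 range). Bray–Curtis is computed on raw
counts without rarefying — an optional `rarefy_to` exists but defaults
off, since subsampling discards data and the downstream uses here are
rank-based or relative. PCoA is classical scaling with negative
eigenvalues reported as-is (no Lingoes/Cailliez correction): the simplest
faithful contract, and the sign and size of negative eigenvalues are
themselves diagnostic. ANOSIM uses mid-ranks, the
$R = (\bar r_B - \bar r_W)/(M/2)$ statistic, and the $+1$-corrected
permutation p-value (never exactly zero); the suite calibrates its null
rejection rate and checks rank-transform invariance.

## 6. The synthetic world

`simulate_dataset()` generates the stated world against which everything
is validated:

* **Metacommunity**: lognormal rank-abundance, $S = 300$ taxa,
  $\sigma_{\log} = 1.5$ — a typical amplicon-survey unevenness; sorted,
  strictly positive, sums to 1.
* **Neutral component**: per-sample Moran process, $N = 1000$ individuals,
  immigration probability $m = 0.1$ per death, burn-in $10N$ steps
  (initialized from the metacommunity, immigration relaxes composition on
  a $\sim N/m$-step scale, so $10N$ steps with this initialization is at
  drift equilibrium for $N \le 10^4$; configurable). Reads are multinomial
  at `depth` (default $10^4$), so columns sum to depth exactly.
* **Niche component**: Gaussian responses
  $w_{kj} \propto p_k\,e^{-(env_j - o_k)^2 / 2\sigma_k^2}$ on an even
  environmental gradient spanning $[-2, 2]$, samples assigned to groups in
  blocks (each group is an environmental window, so filtering produces
  group-level determinism). Planted generalists get $\sigma = 10$
  (flat response), planted specialists $\sigma = 0.08$ — below the
  gradient spacing at 18 samples, so a specialist's expected reads are
  ≥ 95% in its optimal sample, which is what "specialist" means in this
  world — and background taxa $\sigma = 0.8$ (occupying a handful of
  neighbouring samples). Specialist optima snap to actual sample
  environments so every specialist has a realizable habitat.
* **Process mix**: expected per-sample composition
  $(1-\lambda)\,x^{neutral} + \lambda\,w^{niche}$, multinomially sampled —
  mixing expectations rather than counts keeps the noise model uniform in
  $\lambda$.
* **Planted correlations**: `inject_correlated_pair()` resamples two rows
  through a Gaussian copula mapped back onto each row's original value
  multiset, so marginal abundance distributions (and every diversity
  statistic) are untouched while the rank dependence is set exactly.

What the generator does **not** emulate: sequencing error and chimeras,
phylogenetic structure among taxa, spatially explicit dispersal,
compositional artefacts of varying library size (depth is constant by
design), and taxon-taxon interactions beyond the injected copula pairs. A
green test therefore establishes that the estimators recover the stated
generative structure — not that any particular field system satisfies it.

Two caveats discovered by the package's own tests and worth knowing:
the monotone-planting property (wider niche ⇒ larger expected breadth)
holds strictly below saturation but admits ~0.1% wiggle once $\sigma$
exceeds the gradient width, because community renormalization couples a
taxon's profile to everyone else's coverage; and at intermediate process
mixes ($\lambda \approx 0.7$–0.9) the neutral admixture seeds specialist
reads into every sample, so specialist *recall* drops well below the
$\lambda = 1$ figure — a realistic property of mixed assembly, not an
estimator defect.

## 7. Determinism and numerical conventions

Every stochastic entry point takes a `seed`, runs under a temporarily
installed Mersenne-Twister state, and restores the caller's RNG. The
pipeline derives per-stage seeds by hashing the stage name into the master
seed, so adding or reconfiguring one stage cannot perturb another stage's
randomness (verified by a stage-isolation test). Quantiles are type-7;
guild ties break to non-significant; top-N ties break lexicographically;
NST boundary nulls use the equality rule; fitted $R^2$ is never clamped;
PCoA eigenvalues are never corrected. JSON outputs carry a schema version
and round-trip numerics at full double precision.

## 8. Known limitations

* Correlation networks are not compositionally aware (no SparCC/
  SPIEC-EASI); at 18-sample scale and $|\rho| \ge 0.6$ this is standard
  but known to admit compositional artefacts.
* The NCM fit provides no confidence interval on $Nm$ (profile likelihood
  out of scope); seed-level replication in the tests stands in for it.
* NST is taxonomic-only (above), and its absolute level depends on the
  declared null algorithm — cross-study comparisons should compare
  like-for-like contracts, not bare numbers.
* The guild classifier's default null is a community-level randomization;
  per-taxon abundance-conditioned nulls that also preserve matrix fill
  require swap chains, which were excluded for exact reproducibility.
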