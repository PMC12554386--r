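# assemblage

Guild-resolved analysis of microbial community assembly from OTU count
tables.

Soil and other environmental microbiomes are mixtures of habitat
**generalists** — taxa that persist across many sites — and **specialists**
tied to narrow environmental conditions, and the balance of **stochastic**
(drift, dispersal) versus **deterministic** (environmental filtering)
assembly differs between these guilds. `assemblage` packages the standard
tool-chain for dissecting that structure, aimed at microbial ecologists
working with 16S rRNA OTU/ASV tables across treatment groups:

- **Guild classification** — Levins' niche breadth
  *B*<sub>i</sub> = 1 / Σ<sub>j</sub> *P*<sub>ij</sub>² for each taxon
  across *r* sites (*B* = 1: single site; *B* = r: perfectly even),
  compared against a seeded permutation null: taxa strictly above the 97.5%
  null quantile are generalists, strictly below the 2.5% quantile
  specialists, everything else non-significant.
- **Neutral community model (NCM)** — Sloan's model predicts a taxon's
  occurrence frequency from its metacommunity relative abundance *p* under
  drift and immigration: *f*(p) = 1 − I<sub>d</sub>(Nm·p, Nm·(1−p)), with
  I the regularized incomplete beta function and *d* the detection limit.
  Fitted by least squares over *Nm*; reports *R*², the migration rate
  *m* = *Nm*/*N*, and per-taxon Wilson bands (above/within/below).
- **Normalized stochasticity ratio (NST)** — observed pairwise Ruzicka
  (abundance-based Jaccard) dissimilarities compared to a null model that
  reassembles each sample at fixed richness from the regional pool;
  NST > 0.5 reads as stochastic dominance, NST < 0.5 as deterministic
  filtering. Computed per group and per (group × guild) stratum.
- **Co-occurrence networks** — Spearman correlation networks on the top-N
  OTUs (BH-adjusted p < 0.05, |ρ| ≥ 0.6 by default) with the usual topology
  metrics (average degree, density, mean path length over connected pairs,
  greedy modularity, positive-edge fraction) and guild-resolved edge-type
  proportions (G–G / G–S / S–S).
- **Diversity** — natural-log Shannon, Bray–Curtis, classical PCoA
  (negative eigenvalues reported, not corrected), permutation ANOSIM.
- **Synthetic communities with planted truth** — lognormal metacommunity,
  Moran-type neutral dynamics with immigration rate *m*, Gaussian niche
  filtering with per-taxon optima and tolerances, convex process mixing
  (λ = 0 pure neutral … λ = 1 pure filtering), multinomial read depth, and
  copula-planted correlated pairs. Every generator is seed-deterministic,
  so all of the above can be validated against ground truth.

## Worked example

```r
library(assemblage)

# an 18-sample, 3-group community assembled 90% by niche filtering,
# with 15 wide-niche and 15 narrow-niche taxa planted among 150
sim <- simulate_dataset(S = 150, groups = c(SA = 6, PUR = 6, OF = 6),
                        lambda = 0.9,
                        guild_plan = list(n_generalist = 15, n_specialist = 15),
                        depth = 5000, seed = 42, N = 500, burn_in_steps = 5000)

guilds <- classify_guilds(sim$table, n_perm = 500, seed = 42)
guilds
#> guild_classification: 150 OTUs over r = 18 samples (500 permutations, scheme within_sample_shuffle)
#>   generalists: 76, specialists: 6, non-significant: 68

fit_ncm(sim$table)
#> ncm_fit: Nm = 551.3, m = 0.1103 (N = 5000), R^2 = 0.6119, d = 0.0002, 150 taxa / 18 samples

sa <- subset_table(sim$table,
                   samples = names(sim$table$groups)[sim$table$groups == "SA"])
compute_nst(sa, n_reps = 200, seed = 42, group = "SA")
#> nst_result [SA]: NST = 0.444 (ruzicka, proportional_fix null, 200 reps, 15 pairs)
```

Reading the output: 14 of the 15 planted wide-niche taxa are called
generalists (the extra calls are abundant background taxa that the 10%
neutral admixture spreads evenly); only 5 of 15 planted specialists are
recovered at λ = 0.9 because the same admixture seeds their reads into
every sample — at λ = 1 specialist sensitivity exceeds 90% (see the
acceptance tests). The NCM *R*² of 0.61 and the group NST of 0.444 (< 0.5)
are both consistent with the planted filtering-dominated world: a pure
neutral world (λ = 0) pushes NST above 0.5 and *R*² higher still.

The full study-shaped analysis (guilds → diversity / NCM / NST / networks,
per group and per guild, with per-stage files and a versioned JSON report):

```r
report <- run_pipeline(pipeline_config(table = sim$table, seed = 42,
                                       network = list(scope_n = 100),
                                       output_dir = "results"))
compare_groups(report)   # tidy long table: metric x group (x guild), ranked
```

A command-line interface mirrors the stages
(`inst/cli/assemblage simulate | classify-guilds | ncm | nst | network |
diversity | run`); see `assemblage_main()`.

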