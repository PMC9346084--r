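# artemiadapt

Analysis toolkit for common-garden resurrection-ecology studies of thermal
adaptation in the brine shrimp *Artemia franciscana*. The setting: an
ancestral population (cysts collected in 1984, "SFB84") was introduced into
a tropical saltern ~10 °C warmer, and cysts collected 13 and 24 years later
("VCH97", "VCH08") are hatched alongside the ancestor and assayed for
juvenile survival under the two thermal regimes. The package implements the
full downstream statistical pipeline, plus synthetic-data generators with
the same statistical structure so every stage is testable without raw data.

## What it computes

**Tube-level survival models.** Each replicate tube contributes a binomial
outcome (alive of total). `fit_binomial_glmm()` fits
`cbind(alive, dead) ~ factors + (1|family) [+ (1|obs)]` with a logit link
(lme4 Laplace underneath, log-likelihood exposed); `assess_overdispersion()`
is the Pearson-χ²/df ratio, and the observation-level random intercept is
the overdispersion correction. `lr_test()` and `posthoc_pairwise()` (Tukey
single-step adjustment) test predictors; the two thermal regimes are always
analyzed separately.

**Multilevel meta-analysis.** `extract_effect_sizes()` pools the four
"control" subsets of the experiments and extracts, per subset and regime,
each derived population's log odds ratio vs the ancestor,
ln[(p₁/(1−p₁))/(p₀/(1−p₀))], with its sampling variance.
`fit_multilevel_meta()` fits

y_ij = μ + β·pop_ij + u_j + ε_ij,  u_j ~ N(0, τ²),  ε_ij ~ N(0, v_ij)

with experiment j as the random level; τ² is estimated by REML from the
likelihood written in this package (metafor is used only as a test oracle),
and fixed effects are tested by ML likelihood-ratio χ².

**Dominance of the evolved change.** With population time codes 0, 1, 2,
`log_odds_slope()` fits the inverse-variance weighted through-origin slope
of the log-odds trajectory, separately for own-bred populations and for
populations crossed through a common reference maternal line (which carry
the evolved paternal alleles heterozygously). `estimate_dominance()`
returns h = crossed slope / own slope (0 recessive, 0.5 additive) with a
parametric-bootstrap CI.

**Sweep feasibility.** `deterministic_trajectory()` iterates
p′ = [p²(1+s) + p(1−p)(1+hs)] / w̄ (fitnesses 1 : 1+hs : 1+s);
`wright_fisher_trajectory()` adds binomial drift over 2N copies in
frequency space; `sweep_feasibility()` reports whether an allele with given
s, h, N and starting frequency can reach a target frequency in the
available generations.

**Mitotype tracking from pool-seq.** From per-sample base-fraction tables
(fraction of A/C/G/T and coverage at each position of the circular
mitochondrial reference), `call_individual_snps()` calls variants in
individually sequenced samples, `classify_shared_private()` splits them
into shared (≥ 2 carriers) and private (1 carrier),
`define_mitotypes()` groups identical shared-SNP profiles into mitotypes
(singletons = no shared SNPs) with a single-linkage Hamming dendrogram
(Newick), `compute_frequency_envelopes()` assigns each mitotype its
per-year envelope (most frequent shared SNP, or most frequent private SNP
for singletons), and `check_no_recombination_invariant()` verifies that
private-SNP frequency sums never exceed the top shared-SNP frequency.

## Worked example

```r
library(artemiadapt)

# Can a nearly recessive beneficial allele (h = 0.1, s = 0.3) sweep in
# ~100 generations in a population of a million?
rep <- sweep_feasibility(selection_params(s = 0.3, h = 0.1, N = 1e6,
                                          p0 = 1/(2e6), generations = 100),
                         target_freq = 0.5, n_replicates = 100, seed = 1)
print(rep)
#> sweep feasibility: s = 0.3, h = 0.1, N = 1e+06, p0 = 5e-07, G = 100
#>   deterministic final frequency: 9.60991e-06
#>   deterministic generations to reach 0.5: never
#>   stochastic replicates at/above target at G: 0.000 (of 100)
```

The allele barely moves: starting from one copy, 100 generations of strong
but nearly recessive selection leave it at frequency ~1e-5, nowhere near a
sweep — so a large, rapid phenotypic change cannot be explained by such
alleles.

```r
# Dominance from own-bred vs crossed log-odds trajectories
hist <- simulate_adaptation_history(h_true = 0.1, delta = 1, times = 0:2,
                                    sampling_sd = 0.1, seed = 42)
own     <- log_odds_slope(hist[hist$cross_status == "own", ])
crossed <- log_odds_slope(hist[hist$cross_status == "crossed", ])
estimate_dominance(own, crossed, n_boot = 10000, seed = 1)
#> dominance h = 0.104 [95% CI 0.019, 0.193]
#>   own slope 1.0032 (SE 0.0447); crossed slope 0.1038 (SE 0.0447)
```

The own-bred populations gain ~1 log-odds unit per collection epoch while
the crossed ones gain ~0.1: the estimator recovers the simulated dominance
of 0.1 — an almost entirely recessive signal.

```r
# Mitotype structure and frequency envelopes from pooled sequencing
pop <- study_mitotype_population()        # synthetic reconstruction
ds  <- simulate_mito_dataset(pop, mean_coverage = 3000, error_rate = 0.001,
                             seed = 1, replicate_years = c(1984, 1997, 2008))
calls <- classify_shared_private(call_individual_snps(ds$table))
mset  <- define_mitotypes(calls, individuals = as.character(1:10))
print(mset)
#> 6 mitotype(s) over 10 individual(s)
#>   M_10_7: members {10, 7}, 2 shared, 5 private
#>   M_2_4_8: members {2, 4, 8}, 3 shared, 9 private
#>   M_5_6: members {5, 6}, 2 shared, 6 private
#>   M_1: members {1}, 0 shared, 4 private [singleton]
#>   M_3: members {3}, 0 shared, 4 private [singleton]
#>   M_9: members {9}, 0 shared, 4 private [singleton]
compute_frequency_envelopes(mset, ds$table)
#> mitotype frequency envelopes by year:
#>  mitotype    1984    1987    1988    1993    1994    1997    1998    2008
#>    M_10_7 0.21629 0.21934 0.22182 0.23236 0.22248 0.22225 0.21910 0.22017
#>   M_2_4_8 0.17929 0.19003 0.18377 0.18868 0.18107 0.19915 0.19088 0.18887
#>     M_5_6 0.19677 0.20592 0.20341 0.21263 0.20840 0.20763 0.22552 0.19744
#>       M_1 0.07567 0.07898 0.09311 0.07839 0.07902 0.08760 0.07280 0.07926
#>       M_3 0.06143 0.06658 0.07275 0.07518 0.07670 0.07110 0.06770 0.07881
#>       M_9 0.05454 0.04868 0.04777 0.05036 0.05063 0.05129 0.05175 0.04736
```

Seven shared SNPs define three multi-member mitotypes; three individuals
carry no shared SNPs and form singleton groups. The envelopes track each
mitotype's cumulative frequency through 24 years of pooled cyst samples at
~3000× coverage; flat envelopes mean a stable mitochondrial composition.

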