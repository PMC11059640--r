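# cnphylo

Bayesian inference of single-cell tumor phylogenies from copy-number
profiles, under a birth-death model of copy-number evolution.

Single-cell DNA sequencing yields, for each cell, a *copy-number profile*:
integer copy numbers over fixed genomic bins. Somatic copy-number
aberrations (CNAs) accumulate along cell lineages, so these profiles encode
the cells' shared evolutionary history. `cnphylo` is for researchers
studying intra-tumor heterogeneity who want, from a cells-by-bins matrix, a
**rooted ultrametric tree with branch lengths in relative time**, together
with branch-specific mutation rates, ancestral copy-number profiles, and
error-corrected leaf profiles.

## The model in brief

Within each bin, the copy number evolves along a branch as a critical
linear birth-death process: each of the *m* copies present is duplicated or
deleted at per-copy rate *r* (= 1 by default), so transitions *m* → *m* ± 1
occur at rate *mr* and state 0 is absorbing. The transition law has the
closed form (with *a* = *rt*/(1 + *rt*))

    P(i | j, t) = a^(i+j) * sum_{k=1..min(i,j)} C(j,k) C(i-1,k-1) (rt)^(-2k)

for *i*, *j* ≥ 1, and P(0 | j, t) = a^j. Observed copy numbers are Gaussian
around the true state with unknown sd σ. The tree likelihood is a modified
Felsenstein pruning: error densities as leaf partials, and the root weighted
by P(x | 2, d) — descent from a *diploid ancestor* over a root stem of
length *d*, inferred jointly. The posterior over trees, *d*, σ, the
birth-death tree-prior parameters (diversification rate, extinction
fraction) and a random-local-clock rate model is explored by
Metropolis-Hastings MCMC (optionally Metropolis-coupled). A joint
maximum-likelihood dynamic program reconstructs ancestral profiles and
corrects leaf profiles on any fixed tree.

The package also ships the CNA simulator used for validation (Poisson event
counts along branches, sum-of-sines genomic position density, exponential
event sizes, parametric estimation noise) and the evaluation toolkit
(maximum-clade-credibility trees, median node heights, HPD intervals, OLS
tree scaling, branch-recovery-by-decile, normalized pairwise-distance
error, Hamming/L1 profile accuracy).

## Worked example

Simulate data on a known 8-cell tree (height 0.5 in the kernel's relative
time units, medium CNA load), infer the phylogeny, and evaluate it:

```r
library(cnphylo)

set.seed(42)
tree <- random_ultrametric_tree(8, height = 0.5)
events <- simulate_events(tree, c_mult = 125, position_density(a = 0.6))
truth <- events_to_profiles(tree, events, n_bins = 15000)
obs <- subsample_bins(truth$leaf_profiles, 20)

fit <- run_mcmc(obs, mcmc_config(chain_length = 50000), seed = 1)
ps <- posterior_samples(fit)          # 20% burn-in, <= 2000 samples
mcc <- mcc_tree(ps$trees)
med <- median_node_heights(mcc, ps$trees)

beta <- tree_scale_factor(med, tree)  # put inferred heights on true scale
cov <- posterior_coverage(tree, ps$trees, scale = beta)
attr(cov, "coverage")
glance(fit)
beta
```

This run prints (numbers copied from an actual run of the code above):

```
> attr(cov, "coverage")
[1] 0.7142857
> glance(fit)
# A tibble: 1 × 5
  chain_length n_logged acceptance_rate final_log_posterior  seed
         <int>    <int>           <dbl>               <dbl> <dbl>
1        50000     2501           0.247              47681.     1
> beta
[1] 7.504704
```

Five of the seven matched true node heights fall inside their 95% HPD
intervals after scaling (the scale factor `beta` converts inferred relative
time onto the simulation tree's time axis; it is not 1 because the event
intensity per bin differs from the kernel's per-copy rate). The test
suite's recovery study runs the same pipeline on 10 cells with a
200,000-step chain and requires at least 80% coverage. `tidy(fit)` returns
the full scalar trace and `autoplot(fit)` plots it;
`joint_ml_reconstruction()` then yields ancestral and corrected profiles on
the MCC tree.

A command-line surface wraps the same functions
(`inst/scripts/cnphylo simulate | infer | ancestral | summarize |
evaluate`); each subcommand records the seed and configuration in its
output headers.

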