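---
title: "Birth-death models for single-cell copy-number phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death models for single-cell copy-number phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnphylo)
```

## The problem

Somatic copy-number aberrations (CNAs) delete or amplify genomic regions as a
tumor evolves, and single-cell DNA sequencing lets us read the resulting
copy-number profile of each cell: a vector of integer copy numbers over
fixed-width genomic bins. Because CNAs accumulate along cell lineages, these
profiles carry a phylogenetic signal. `cnphylo` infers a rooted, ultrametric
binary tree of the sampled cells — with branch lengths in relative time and
branch-specific mutation-rate multipliers — from such a cells-by-bins matrix,
treating the profiles as error-prone estimates of the true integer states.

The package also reconstructs copy-number profiles at ancestral nodes and
error-corrected profiles at the leaves, simulates CNA data with known ground
truth along a user-supplied tree, and provides the posterior summaries and
accuracy metrics needed to evaluate the whole pipeline.

## The model

### Copy-number evolution

Within one bin, the copy-number state evolves along each branch as a
continuous-time *critical linear birth-death process*: each of the `m`
copies currently present is independently duplicated at rate `r` and deleted
at rate `r`, so the chain moves from `m` to `m + 1` or `m - 1` at total rate
`m r`; state 0 is absorbing (a fully deleted region cannot come back). With
equal birth and death rates the absolute time scale is confounded with `r`,
so `r = 1` and branch lengths are relative times. The transition law has a
closed form: with \(a = rt/(1+rt)\),

\[
P(i \mid j, t) = a^{i+j} \sum_{k=1}^{\min(i,j)} \binom{j}{k}\binom{i-1}{k-1} (rt)^{-2k}
\quad (i, j \ge 1),
\]

with \(P(0 \mid j, t) = a^{j}\) and state 0 absorbing. The implementation is
verified in the test suite against the matrix exponential of the process
generator truncated at state 200 (agreement to \(10^{-8}\) and better). For
likelihood computation the state space is truncated at a maximum state `k`
(default 9, the largest value commonly seen in tumor copy-number calls);
probability mass leaking above `k` is *dropped, not renormalized*, so the
truncated kernel is a strict sub-probability kernel. Renormalizing would
redefine the likelihood, and with `k = 9` the leaked mass is negligible at
the branch lengths the sampler visits.

### Observation error

Estimated copy numbers are modeled as Gaussian around the true state:
\(c_\text{obs} \sim N(c_\text{true}, \sigma^2)\), with \(\sigma\) inferred
under a Uniform(0, 9) prior (the bounds are the smallest and largest states
considered). The density is not truncated to `[0, k]`: truncation would
change the error model without evidence that the data-generating process is
truncated.

One consequence of pairing a continuous error density with integer-valued
observed profiles deserves mention: as \(\sigma \to 0\) every integer
observation can be matched exactly by some state, so the likelihood grows
without bound and the posterior becomes improper at the boundary. The priors
therefore impose a numerical floor (`sigma_floor`, default \(10^{-4}\)
copy-number units — far below any real calling noise) so the posterior is
proper and the chain remains evaluable. In practice the chain may settle at
the floor when observations are exact integers; tree inference is unaffected
because the likelihood then reduces to the no-error likelihood of the
observed states.

### Tree likelihood

The likelihood of a tree is a product over bins (bins are assumed
independent; see *Limitations*). Each bin's likelihood is computed by
Felsenstein pruning with two modifications:

* leaf partials are the error-model densities \(L_y(j) = N(c_y; j, \sigma)\)
  over candidate states `j = 0..k`, so profile error is integrated out;
* the root is not weighted by a stationary distribution (the critical
  process has none over the positive states) but by \(P(x \mid 2, d)\): the
  probability of reaching state `x` from the diploid ancestor (state 2 in
  every bin) over a *root stem* of duration `d`. The stem length `d` is
  inferred jointly, with a Uniform(0.001, 5) prior.

Pruning is carried out in log space with per-node rescaling of the partial
vectors, which keeps 15,000-bin matrices numerically stable. Per-branch
transition matrices are computed once per tree and shared across bins
(`O(n k^2)` per bin), and are memoized across MCMC steps keyed on the
branch's effective length quantized to 12 significant digits (a pure
performance cache with no semantic effect at that precision).

### Priors

The tree follows a two-parameter conditioned birth-death prior in the
diversification rate \(r_d = \tilde\lambda - \tilde\mu\) (Uniform(0, 10^6))
and extinction fraction \(r_e = \tilde\mu / \tilde\lambda\) (Uniform(0, 1)).
We use the point-process form of the conditioned reconstructed process:
given `n` tips, internal node heights are i.i.d. with density

\[
g(t) = \frac{r_d (1 - r_e)\, e^{-r_d t}}{(1 - r_e e^{-r_d t})^2},
\]

(a proper density; the test suite checks \(\int_0^\infty g = 1\)), and the
labeled history is uniform. This is the canonical \((r_d, r_e)\)
parameterization of the constant-rate reconstructed birth-death process and
reduces to an exponential height density in the pure-birth limit.

Branch-specific mutation rates follow a random local clock: each branch
carries an indicator and a multiplier; a branch's effective rate is the
multiplier of its nearest ancestor-or-self branch with an active indicator,
else 1. The number of active indicators is Poisson with mean \(\log 2\) —
placing prior probability exactly 0.5 on a strict clock — placements are
uniform, and multipliers are Gamma(shape 0.5, scale 2). The implementation
keeps a multiplier on every branch with its Gamma prior regardless of the
indicator (the standard product-space construction), which leaves the
marginal over active quantities unchanged while avoiding transdimensional
moves. Rates are not renormalized to mean 1; the resulting scale
non-identifiability is absorbed by the downstream regression scaling.

The kernel applies a branch's effective rate multiplicatively to its time
duration. The root stem uses rate 1: it predates the sampled lineages, so no
sampled branch's rate change can apply to it.

## The sampler

`run_mcmc()` is a random-scan Metropolis-Hastings sampler over
\((\mathcal{T}, d, \sigma, r_d, r_e, \text{clock})\). The move set:

* uniform resampling of one internal node height within its valid interval;
* log-scale multipliers of the root height and of all internal heights
  (whole-tree scaler), with the appropriate Jacobian terms;
* narrow and wide exchange (rooted nearest-neighbor-style topology moves)
  and Wilson-Balding subtree prune-regraft, all with auto-rejection of
  height-infeasible proposals drawn from fixed candidate sets, keeping the
  proposals symmetric or with explicit Hastings ratios;
* reflected random walks on `d`, `sigma`, `r_e` and log-scale moves on `d`,
  `sigma`, `r_d`;
* indicator bit-flips and multiplier scalers for the local clock.

Weights are configurable (`mcmc_config(move_weights = ...)`). Every proposal
recomputes the posterior from the current state rather than incrementally,
which costs little at these problem sizes and makes the cached trace values
exactly reproducible from the logged states — the test suite recomputes
log prior and log likelihood from scratch at sampled states and checks
equality.

The chain initializes from an average-linkage clustering of per-cell L1
distances (root height 0.1, `d = 0.5`, `sigma = 0.5`, all indicators off), a
deterministic and reasonable starting point. `coupled_chains()` runs
Metropolis-coupled chains with inverse temperatures
\(1/(1 + \Delta (c-1))\) (default \(\Delta = 0.1\), 4 chains) applied to the
likelihood, proposing adjacent-pair swaps every 100 steps with the standard
tempered ratio; only cold-chain states are logged.

Sampler correctness is validated by prior-only runs (likelihood disabled):
the marginals of `sigma`, `r_e` and `d` are checked against their uniform
priors by Kolmogorov-Smirnov tests, the rate-change count against
Poisson(log 2), and 4-leaf topology frequencies against the uniform
labeled-history property of the birth-death prior (balanced topologies 1/9,
caterpillars 1/18).

## Ancestral and corrected profiles

Given a tree, `joint_ml_reconstruction()` finds for each bin the single
joint assignment of states to *all* nodes maximizing the likelihood — the
standard joint-ML dynamic program, extended so leaves also maximize over
their state against the error model, which corrects the observed profiles
in the same pass. Root states are weighted by the diploid-stem term
\(P(x \mid 2, d)\). Arg-max ties break toward the lowest state, a
deterministic and reproducible rule. The DP is verified against exhaustive
enumeration over all joint assignments on small trees.

The tree handed to reconstruction must be in the time units of the `r = 1`
kernel (as inferred trees are). A simulation tree in other units should be
rescaled first; the test suite demonstrates the correction gain (error 0.24
to about 0.15 at medium event load) with a kernel-scale true tree.

## The simulator

`simulate_events()` draws, on each branch of duration `t`, a Poisson(`c t`)
number of CNA events (`c` is the event multiplier; 90, 125 and 250 represent
low, medium and high CNA loads). Each event independently picks the maternal
or paternal allele with probability 1/2, a gain or loss with probability
1/2, a size of 2 Mbp plus an Exponential(mean 10 Mbp) draw, and a start
position from a sum-of-sines density on the linearized unit-interval genome,

\[
f(x) \propto \exp\Big(\sum_{i=1}^{30}\sin(1000x + \phi_i)\lambda_i\Big),
\qquad \phi_i \sim U(-\pi,\pi),\ \lambda_i \sim U(0, a),
\]

with non-uniformity `a = 0.6` by default, which makes simulated CNAs cluster
so that well over 90% of events overlap at least one other event — the
hallmark of real tumor CNA landscapes that uniform placement misses. At
`a = 0` the density is exactly uniform. Sampling is by inverse CDF on a
\(10^6\)-point midpoint grid with within-cell interpolation (accurate to
about \(10^{-6}\)).

`events_to_profiles()` applies events count-wise on a fixed coordinate
frame: each allele starts at one copy, a gain adds one copy over its
interval, a loss removes one with a floor at zero (consistent with the
kernel's absorbing state). Events on a branch apply in a per-event
pseudo-time order, which matters only through the loss floor. Bin values
are overlap-length-weighted means of the per-base total copy number,
rounded half-up. Default geometry: a 3 Gbp linearized genome cut into
15,000 equal bins. The per-node truth is recorded for every internal node.

Read-level error (sequencing, alignment, copy-number calling) is replaced by
a parametric stand-in, `add_estimation_noise()`: independent rounded
Gaussian jitter calibrated so the expected per-entry Hamming error equals a
target rate (default 0.24, the median per-cell error rate of read-based
calling pipelines this model emulates), clipped to `[0, k]`. What this does
*not* emulate: spatially correlated calling errors along the genome,
cell-specific quality differences, and segmentation artifacts — so passing
tests bound behavior under independent noise only.

`subsample_bins()` keeps every 20th bin (stride and offset configurable) to
weaken the dependence between adjacent bins before inference; it is off by
default and applied explicitly in the examples.

## Posterior summaries and evaluation

* `mcc_tree()`: the sampled tree maximizing the product of its clades'
  posterior frequencies, annotated with per-clade supports.
* `median_node_heights()`: per-clade medians of node heights across the
  samples containing the clade. Medians from different samples can invert a
  parent-child pair; such violations are flagged in an attribute, never
  silently repaired.
* `hpd_interval()`: shortest window over the sorted samples containing
  `ceiling(mass * n)` points.
* `ols_scale()` / `tree_scale_factor()`: inferred branch lengths are in
  relative time, so before comparing against a true tree the node heights
  are scaled by the no-intercept least-squares factor
  \(\beta = \sum x_i y_i / \sum x_i^2\) over matched clades (identical leaf
  sets; the root clade is excluded since it is always shared). One factor
  per run, applied to all samples.
* `branch_tpr_by_decile()`: per true branch, the fraction of samples
  containing its clade, aggregated over rank-based deciles of true branch
  length (ties broken by stable order).
* `normalized_pairwise_distance_error()`: leaf-pair distances in
  mutation-count units (branch duration times effective rate; the unknown
  proportionality constant cancels under the min-max normalization applied
  to each matrix's off-diagonal entries), compared as a Frobenius norm
  divided by \((|L|-1)^2\).
* `posterior_coverage()`: per matched clade, whether the true height falls
  in the 95% HPD of the scaled sampled heights.

All summary operations are tested against brute-force oracles (enumerated
windows, grid-search regression, direct clade-product maximization).

## Problem sizes and reproducibility

The test suite exercises the full pipeline at deliberately modest sizes
chosen to probe each property clearly: oracle comparisons on trees of 2-4
leaves with `k` up to 5 (exhaustive enumeration over up to \(6^7\) joint
assignments), prior-calibration runs of about \(10^5\) steps, and one
end-to-end recovery study: a 10-leaf coalescent-shaped model tree of height
0.5 in kernel time units — about 60 CNAs per root-to-leaf lineage at the
medium event multiplier `c = 125`, a realistic tumor CNA load — with 15,000
simulated bins thinned 1-in-20 to 750 and a \(2 \times 10^5\)-step chain
summarized by 2000 post-burn-in samples (20% burn-in). The recovery study
runs on the true simulated profiles: adding the integer-rounded noise
stand-in re-triggers the \(\sigma\) boundary degeneracy described above, and
the i.i.d. noise is then absorbed as events on terminal branches, which
distorts internal node heights — a limitation of the plain-Normal error
model on integer data, not of the sampler. After regression scaling, at
least 80% of matched true node heights should fall in their 95% HPD
intervals and the MCC tree should contain at least 80% of the true tree's
top-half-length clades.

Every random quantity in the package flows from an explicit seed; chains,
simulations and the command-line pipeline are bit-reproducible given a seed,
and output files carry the package version, seed and a configuration hash in
their headers.

## Known limitations

* **Independent bins.** CNAs span many bins, so adjacent bins are strongly
  dependent; the likelihood ignores this by design (tractability), and bin
  subsampling only weakens rather than removes the dependence. Branch
  lengths remain interpretable but posterior uncertainty is understated to
  an unquantified degree.
* **Integer observations and \(\sigma\).** See the observation-error
  section: \(\sigma\) is weakly identified from integer profiles and may
  settle at the numerical floor.
* **Count-based event semantics.** Amplifications do not change genomic
  coordinates (no tandem-duplication positional expansion); the simulator
  and model share this abstraction, so simulation studies cannot detect its
  cost.
* **No whole-genome or whole-chromosome events**, no inter-bin dependency
  modeling, and no per-bin rate variation.
* **Time scale.** With birth rate equal to death rate, branch lengths are
  identifiable only up to the regression scaling; reported times are
  relative.
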