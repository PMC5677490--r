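---
title: "Selective-regime models of size-corrected limb traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective-regime models of size-corrected limb traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouregimes)
```

## The analysis this package implements

Limb skeletons of ecologically specialised mammals — climbers, diggers,
swimmers — carry measurable signatures of their locomotor habit. The question
this package addresses is whether such habits act as *selective regimes* on
skeletal proportions: do lineages in different habits evolve toward different
phenotypic optima, and where on the phylogeny do the regimes shift?

The pipeline has five stages:

1. **Size correction** (`species_means`, `size_residuals`). Specimen-level
   linear measurements (mm) are averaged per species; each log trait is
   regressed by OLS on the log geometric mean of all 14 traits, and the
   residuals are the size-corrected shape variables.
2. **Ordination** (`trait_pca`, `broken_stick`). Covariance-matrix PCA of the
   residuals; components whose variance proportion strictly exceeds the
   broken-stick expectation `(1/p) * sum(1/i, i = k..p)` are retained.
3. **Trait-diversification models** (`fit_evo`). Six Gaussian models fitted
   to one PC score vector at a time: single-rate Brownian motion (BM1),
   multi-rate BM (BMS), single- and multi-optimum Ornstein–Uhlenbeck
   (OU1/OUM), early burst (EB) and white noise (WN). Habit-based regimes for
   BMS/OUM are integrated over stochastic character mappings
   (`sample_mappings`, `fit_over_mappings`).
4. **Unconstrained shift detection** (`run_shift_chain`, `shift_posterior`,
   `shift_painting`). Reversible-jump MCMC over the number, branch locations
   and values of shifts in the OU optimum; branches whose posterior shift
   probability reaches 0.20 are deemed significant and converted into a
   fixed regime painting for comparison with the a-priori models.
5. **Model comparison and adequacy** (`build_comparison_table`, `pmc_test`).
   AICc with Akaike weights, phylogenetic half-life annotation, and a
   parametric-bootstrap likelihood-ratio test of the best model against the
   Brownian null (phylogenetic Monte Carlo).

## The models

All six models are Gaussian processes on a rooted ultrametric tree with
branch lengths in My, so each is fully characterised by the tip expectation
vector and tip covariance matrix (`evo_moments`):

* **BM1**: `E = root`, `Cov[i,j] = sigma2 * t_shared(i,j)`.
* **BMS**: shared time is accumulated regime by regime along the painted
  branches, `Cov[i,j] = sum_r sigma2_r * t_shared_in_r(i,j)`.
* **OU1/OUM**: `Cov[i,j] = sigma2/(2 alpha) * exp(-alpha d_ij) *
  (1 - exp(-2 alpha t_shared))`, the root-conditioned form valid for
  ultrametric trees; expectations are Hansen exponential weightings of the
  optima along each root-to-tip lineage, with the root lineage anchored at
  the root regime's optimum.
* **EB**: BM with rate decaying as `exp(r t)`, `r <= 0`;
  `Cov[i,j] = sigma2 (exp(r t_shared) - 1)/r`, reducing exactly to BM1 at
  `r = 0`.
* **WN**: iid Normal tips, no tree structure.

Parameter counts used in AICc are: BM1 and WN `k = 2`; OU1 and EB `k = 3`;
OUM `k = 2 + m` and BMS `k = 1 + m` for `m` regimes, with the OU root fixed
at the root regime's optimum. These counts reproduce published AICc values
recomputed from printed log-likelihoods for the single-regime models; the one
published multirate-BM row known to be inconsistent with any natural `k` is
flagged in the package documentation and not treated as a target.

**Half-life.** The attraction rate is reported as the phylogenetic half-life
`t1/2 = ln(2)/alpha`. A caution for readers comparing against published
tables: a half-life computed from an already-rounded alpha can disagree in
the third digit with one computed before rounding (e.g. `ln(2)/0.26 = 2.666`
may appear in print as 2.65); this package always computes the exact
transform of whatever alpha it is given.

## Fitting: profiling instead of full-dimensional search

Maximum-likelihood estimation exploits the linear-Gaussian structure: for any
fixed covariance shape, the optima/root enter the mean linearly and the
overall `sigma2` scales the covariance, so both are profiled exactly
(GLS mean, `sigma2 = quadratic form / n`). What remains is

* nothing for BM1/WN (closed form),
* a 1-D bounded search over `alpha` (OU1/OUM) or the decay rate (EB),
  solved by deterministic golden-section search on the log scale,
* an `(m-1)`-D multistart L-BFGS-B over rate ratios for BMS.

`alpha` is searched in `[1e-6, 50/height]`: on a handful-of-My tree the
likelihood is flat in `alpha` beyond a few half-lives per tree depth, and the
profile parameterisation removes the `alpha`–`sigma2` ridge that makes naive
full-dimensional multistarts unreliable. If the Hansen weights of a deep
regime vanish at every tip (large `alpha`), the GLS design is rank-deficient;
a pseudo-inverse drops the unidentifiable optimum rather than failing.

## Stochastic character mapping

The 4-state locomotor habit is modelled by an equal-rates Mk process
(all-rates-different available), fitted by the pruning algorithm with a
uniform root prior — both choices are explicit substitutes for unstated
conventions, switchable in the API. Mappings are sampled exactly:

1. node states by conditional sampling from the pruning partials, root to
   tips;
2. the path within each branch by *uniformization*, conditioned on the branch
   endpoints (the number of candidate jumps is drawn from its exact
   endpoint-conditioned distribution, jump times are uniform order
   statistics, virtual jumps are collapsed).

Uniformization is exact and uniformly fast, so no rejection-sampling pre-step
is used. Every sampled painting conserves segment sums per branch and agrees
with the observed tip states by construction; both invariants are asserted
over thousands of mappings in the tests, and the sampler's regime occupancy
is cross-checked against an independent implementation (`phytools`).

Averaging over mappings follows the standard protocol: the multi-regime model
is refitted to each sampled history (500 by default) and parameter means are
taken across mappings; non-converged refits are excluded and counted.

## The reversible-jump shift sampler

The unconstrained model is a single-`alpha`, single-`sigma2` OU process whose
optimum may shift at most once per branch, at an unknown position, to an
unknown value. Priors (all overridable):

* shift count: conditional Poisson, mean `lambda = 1`, truncated at half the
  tip count, branch sets uniform given the count;
* position: uniform along the branch (rootward-origin, half-open);
* optima and root optimum: Normal(data mean, 2 x data sd);
* `alpha` and `sqrt(sigma2)`: half-Cauchy.

Moves: birth/death (Green ratio; new optima proposed from the prior so the
dimension-matching terms cancel), a within-branch position slide, a
**relocate** move that reassigns an existing shift to a uniformly chosen free
branch, and scalar updates of `alpha`, `sigma2` and the optima. Relocation
was added after observing chains trapped in a *complement-shift* mode — on an
ultrametric tree the root-anchor weight `exp(-alpha T)` is tiny, so painting
the complement of a clade is nearly equivalent to painting the clade with the
optima relabelled; independence relocation hops between such modes directly,
where birth/death alone must pass through an improbable two-shift state. The
sampler is validated against its own prior (likelihood switched off, shift
counts compared with the conditional-Poisson mass) and by recovery studies.

Chain defaults follow the production protocol typical of this kind of
analysis (1,500,000 iterations); the package's studies and tests use
20,000-iteration chains with 30% burn-in and thinning 10, which the recovery
experiments show is ample for a single strong clade shift at 40 tips.
Per-branch posterior shift probabilities are simple post-burn-in sample
fractions; a branch is called significant at posterior probability 0.20,
the working convention for this model class.

## Model adequacy (phylogenetic Monte Carlo)

`pmc_test` simulates data under the fitted null (BM1) and the fitted best
model, refits both models to every simulated dataset, and collects the two
bootstrap distributions of the likelihood ratio `2 (lnL_best - lnL_null)`.
Percentile 95% intervals are used (the plain reading of an unqualified
"confidence interval"). The observed LR is then located: inside the null
interval, the data are indistinguishable from Brownian motion; inside the
best-fit interval, consistent with that model; outside both, neither model is
adequate — typically a sign the tree carries too few taxa for the contrast.
The study protocol uses 10,000 iterations; the package's calibration tests
use 500 iterations over 40 outer replicates, which bounds the Monte-Carlo
error of the coverage estimate at about 3.5 percentage points.

## The synthetic-data generator

`simulate_dataset` emulates the structure of the empirical system at known
ground truth: a 40-tip pure-birth tree of height 16 My; 4-state equal-rates
habit evolution (0.02 per-pair transitions/My, giving on the order of a dozen
habit changes per tree — enough homoplasy to make ancestral habits genuinely
uncertain); and 14 log-normal traits built as

```
log trait_ij = intercept_j + slope_j * s_i + d_ij ,
```

with `s` a Brownian log size factor (rate 0.02/My, spanning roughly a
seven-fold linear size range at the tips, as in a weasel-to-otter clade),
near-isometric slopes, intercepts at realistic mm magnitudes, and `d` the
habit-structured OU deviations (`alpha = 0.26`, stationary sd 0.05, i.e. 5%
shape deviations). Species are sampled as 1-6 specimens with 5% measurement
CV.

Scenario A shifts the deviation optima by 2 stationary sds per trait on the
stem of a mid-sized clade (5-10 tips, chosen deterministically from the
tree), and assigns that clade the scansorial habit. The shift pattern is a
**balanced** gracile-versus-robust contrast (+: bone lengths, deltoid ridge,
ulnar ML diameter; -: shaft diameters, olecranon, epicondylar breadth; seven
of each). Balance matters: a contrast whose entries do not sum to zero moves
the geometric mean of shifted species, leaks into the allometric regressions,
and smears the shift onto similarly sized non-clade species — an instructive
artifact, but not the clean clade shift the scenario is meant to provide.

Scenario B shifts two singleton terminal branches in opposite directions.
A shift halfway along a pendant branch is attenuated by
`1 - exp(-alpha t/2)` before it reaches the tip, so scenario B controls the
*expressed* displacement (4 stationary sds at the tip, emulating taxa at the
extremes of the trait axis) and restricts eligible branches to at least
median pendant length. Scenario NULL evolves deviations under single-regime
BM.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the methods assume — it does not reproduce real
measurement values, real topologies, or trait-trait correlations beyond the
shared size factor and the shift contrast. One caveat is deliberate and
worth knowing: under the Brownian NULL scenario, ordinary (non-phylogenetic)
PCA still shows apparent clade separation (mean point-biserial correlation
around 0.4 with a mid-sized clade), because Brownian data are deeply
autocorrelated on the tree. This is the classic argument for caution with
standard PCA on comparative data; the pipeline keeps standard PCA
deliberately, mirroring the analysis it implements, and the tests assert the
honest property — null pseudo-structure stays far below the true-shift
signal — rather than an unattainable near-zero correlation.

## Numerical conventions

* Ages run backwards from the present (tips at age 0); positions on branches
  are rootward-inclusive, tipward-exclusive.
* Ultrametricity tolerance is relative (`1e-6` x height), since published
  dated trees carry rounded lengths. Polytomies are rejected by default; an
  opt-in resolver inserts `1e-8` My branches.
* Paintings derived from node states split parent-child regime transitions
  at the branch midpoint — a deterministic, symmetric convention. Sampled
  mappings carry their own change points and never use the midpoint rule.
* PCA is on the covariance matrix (residuals are already dimensionless log
  deviations on a common scale); a correlation-matrix mode exists for
  sensitivity checks. Natural logs throughout. Component signs are fixed by
  making each component's largest-magnitude loading positive.
* Broken-stick significance uses strict exceedance; trailing tiny components
  can exceed their (tiny) stick expectations, so non-contiguous exceedance
  sets are reported as-is with a warning — only the leading block is
  interpretable.
* All simulation draws are exact (Cholesky of the model covariance), and
  every stochastic function takes a seed, with the RNG state restored
  afterwards; a master seed fans out to fixed per-stage child seeds in the
  pipeline drivers.

## Test problem sizes

The package's studies are sized for a single CPU: likelihood oracles run on
all trees of 3-6 tips against dense matrix inversion; parameter recovery uses
200 replicates on the 40-tip/16-My fixture; shift recovery uses 20 seeded
20,000-iteration chains (scenario A) and 5 seeded 60,000-iteration chains
(scenario B, where singleton shifts mix more slowly); adequacy calibration
uses 40 outer replicates of 500-iteration bootstraps; mapping invariants are
asserted over 50 mappings on each of 20 datasets.

## Known limitations

* Univariate fits of PC scores, by design; no multivariate OU, no
  measurement-error variance terms.
* The OU likelihood uses the root-conditioned stationary form and therefore
  requires ultrametric trees (extant taxa only; no fossil tips).
* Shifts move only the optimum; `alpha` and `sigma2` are shared across
  regimes in the unconstrained model.
* No marginal-likelihood estimation or parallel tempering; a single chain
  with relocation moves suffices for the regimes studied here, but heavily
  multimodal posteriors on larger trees would warrant more.
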