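---
title: "Bayesian information borrowing in basket trials: models, engines, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian information borrowing in basket trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketborrow)
```

## The problem

A basket trial tests one therapy simultaneously in several disease cohorts
("baskets"), each typically a small single-arm study with a binary tumor
response endpoint. Basket $j$ enrolls $n_j$ patients and observes $y_j$
responders,

$$y_j \mid n_j, \pi_j \sim \mathrm{Bin}(n_j, \pi_j), \qquad j = 1, \dots, J,$$

and the drug is declared promising in basket $j$ when the posterior
probability of beating a basket-specific reference rate exceeds a threshold:
$\Pr(\pi_j > \pi_{0j} \mid \mathrm{data}) > q_j$. With ten or twenty patients
per basket a stratified analysis is hopelessly imprecise; because the same
drug is tested everywhere, it is natural to let the baskets inform each
other. `basketborrow` implements the standard Bayesian machinery for doing
so, and the simulation tooling needed to understand what borrowing does to
frequentist operating characteristics.

## What is borrowed, and how

Each basket effect is transformed, $\gamma_j = h(\pi_j)$, and the
transformed effects are modeled as a random sample from a population
distribution $G(\theta)$. The transformation chooses *what* is shared
(`transform_spec()`): the raw rate, its log odds, the log-odds increment
over the reference rate $h(\pi_j) = \mathrm{logit}(\pi_j) -
\mathrm{logit}(\pi_{0j})$ (the right choice when reference rates differ
across baskets), or the hypothesis indicator $1(\pi_j > \pi_{0j})$.
Probabilities within $10^{-12}$ of 0 or 1 are rejected rather than clipped,
so transformation errors surface at the boundary instead of being silently
absorbed.

The prior chooses *how* sharing happens (`prior_spec`):

* `independent_normal(0, 100)` - effectively no borrowing; each basket is
  analyzed on a nearly flat prior.
* `hier_normal()` - $\gamma_j \sim N(\mu, \sigma^2)$ with hyperpriors on
  $(\mu, \sigma)$. The population standard deviation $\sigma$ is the
  borrowing dial: $\sigma = 0$ pools completely, large $\sigma$ decouples
  the baskets. Because $J$ is small, $\sigma$ is weakly identified and its
  hyperprior matters; half-normal and half-$t$ priors on $\sigma$ are
  provided alongside the conjugate inverse-gamma on $\sigma^2$.
* `mixture_normal(K)` - a finite normal mixture, equivalently latent
  subgroups within which borrowing is concentrated; guards against
  borrowing across clearly heterogeneous baskets.
* `partition_bma()` - Bayesian model averaging over all set partitions of
  the baskets, pooling within subsets; a data-driven compromise between
  complete pooling and stratification.
* `indicator_borrow()` - borrowing at the hypothesis level via a shared
  Bernoulli rate on $1(\pi_j > \pi_{0j})$, with truncated-beta conditional
  priors for the rate on either side of $\pi_{0j}$.

Three named configurations on the logit-increment scale,
`named_prior("prior_I"|"prior_II"|"prior_III")`, correspond to no, moderate
($\sigma \sim$ Half-N(3)) and strong ($\sigma \sim$ Half-N(0.3)) borrowing
with $\mu \sim N(0, 100^2)$; these are the benchmark settings used
throughout the tests. The $\mu$ hyperprior is taken at face value from the
benchmark description; nothing in the package depends on its exact (very
diffuse) scale.

Where the benchmarks leave parameters unstated, the defaults are fixed
once here and not revisited: the mixture uses a symmetric Dirichlet(1) on
weights and the same half-normal scale hyperprior per component, with no
ordering constraint on component labels (all reported quantities are
label-invariant); the indicator model uses Beta(1,1) everywhere; the
partition prior is uniform over partitions with an optional
$\exp(-\lambda \cdot \#\mathrm{subsets})$ tilt, $\lambda = 0$ by default.
The partition model's within-subset prior is $N(0, 2^2)$ on the
logit-increment scale rather than something very diffuse: marginal
likelihoods are Bartlett-sensitive, and an extremely wide within-subset
prior would mechanically force the fully pooled partition to dominate.
A scale of 2 still admits response-rate increments far beyond anything
plausible clinically.

## Posterior computation: two engines

**MCMC.** The default sampler (`fit_basket()`) is adaptive
Metropolis-within-Gibbs on $(\gamma_1, \dots, \gamma_J, \mu, \log\sigma)$:
the $\gamma_j$ are conditionally independent given the hyperparameters and
are proposed jointly with componentwise acceptance; $\mu$ uses its exact
conjugate normal draw; $\log\sigma$ uses a Gaussian random walk. Proposal
scales adapt during burn-in toward 40% acceptance and are frozen
afterwards. Two further updates are interweaved each iteration for the
hierarchical model: a joint translation of $(\mu, \gamma)$ and a joint
rescale of $(\sigma, \gamma - \mu)$ - the ancillarity-sufficiency trick
that removes the funnel-shaped autocorrelation between the population
scale and the effects. The mixture adds a Gibbs step on the latent labels
and a conjugate Dirichlet step on the weights. Defaults are 4 chains of
10,000 iterations with 50% burn-in; chain $c$ seeds an independent
substream derived from (seed, $c$), chains run sequentially, and reruns
with the same configuration are bit-identical. Split-$\hat R$ and
autocorrelation-based effective sample sizes are reported per quantity;
$\hat R > 1.05$ is recorded as a warning in the summary rather than an
exception.

Exceedance probabilities from the sampler are Rao-Blackwellized: instead
of counting indicator draws, the conditional probability
$\Pr(\gamma_j > c \mid \mu, \sigma, y_j)$ is computed by the
one-dimensional integrator at each retained draw and averaged. This
removes most of the Monte-Carlo noise exactly where decision thresholds
near 0.95 make it most damaging.

**Deterministic quadrature.** For the independent-normal and
hierarchical-normal models, `fit_oracle()` computes posteriors to
quadrature accuracy: an outer Riemann sum over a $(\mu, \log\sigma)$ grid
($201 \times 201$ by default, $\mu \in [-15, 15]$, $\sigma \in [0.01,
50]$) weighted by the marginal likelihood, with per-basket inner integrals
over $\gamma$. Each inner integral uses Gauss-Legendre panels recentred at
the conditional mode (found by damped Newton on the strictly concave
integrand) and *split at the decision cutoff*, so tail probabilities carry
full quadrature accuracy instead of the $O(h)$ error an indicator-weighted
rule would give. The integration window is the union of a $\pm 8$
Laplace-scale neighborhood of the mode and a $\pm 7 \sigma$ prior
envelope, which covers the flat-likelihood directions that arise when
$y_j = 0$ or $y_j = n_j$. Rate means and credible intervals come from the
mixture density on a fixed $\gamma$ grid ($[-12, 12]$, 241 points); mass
beyond the grid edges (possible only under near-flat priors with boundary
counts) is treated as atoms at the edges, which map to rates within
$10^{-4}$ of 0 or 1. Credible intervals are equal-tailed 2.5/97.5
percentiles throughout; highest-density intervals are deliberately out of
scope.

The two engines are developed independently enough to cross-check each
other - the test suite requires their exceedance probabilities to agree
within 0.015 under the default sampler budget - and the quadrature engine
is itself validated against brute-force `stats::integrate` computations on
small cases.

Because the inner integrals depend only on $(y, n, \pi_0,
\mathrm{cutoff})$ and the grid - not on the hyperprior - the simulator
precomputes them for all $y = 0, \dots, n$ once and reuses them across
replicates, scenarios, priors and candidate thresholds. A full
1000-replicate scenario evaluation then costs seconds.

## Decisions, stratified comparator, futility

Efficacy uses the strict rule $\Pr(\pi_j > \pi_{0j} \mid \mathrm{data}) >
q_j$ (`decide()`). The no-borrowing comparator (`stratified_analysis()`)
is $y_j/n_j$ with exact Clopper-Pearson intervals from beta quantiles.
Interim futility (`futility_check()`) halts accrual in basket $j$ when
$\Pr(\pi_j > \tilde\pi_{0j} \mid \mathrm{interim}) < c_{jr}$, strict
inequality, where $\tilde\pi_{0j}$ is typically the midpoint of the
reference and target rates; the exceedance is computed by the same
inference machinery with the substituted reference. Stopping is binding
and basket-local; the final analysis uses each basket's data at stopping.
Whether a stopped basket may still be declared promising at the final
analysis is not pinned down by the rule itself; the package's default is
that it may not (a futility stop is a final non-rejection), which is the
interpretation a trial protocol would normally adopt, and it is
configurable in the simulator.

## Operating characteristics and threshold calibration

The simulator (`operating_characteristics()`) draws $y_j \sim
\mathrm{Bin}(n, \pi_{\mathrm{true},j})$ per scenario from patient-level
uniform draws, so common random numbers are exact across scenarios,
design variants and candidate thresholds; paired comparisons (e.g. the
monotonicity of empirical FWER in $q$) then hold deterministically, and
each reported percentage carries its binomial Monte-Carlo standard error.
The bundled `basket_fixture("scenarios")` defines the six benchmark
scenarios - global null, global alternative, and four mixed
configurations over 4 baskets with reference rate 0.2 - and the study
conditions are 20 patients per basket and 1000 replicates. These defaults
*are* the benchmark conditions and are not tuning knobs.

Weak-control calibration (`calibrate_weak()`) simulates the global null,
computes each replicate's maximum exceedance probability $T_r$, and
returns the smallest threshold on a 0.001 grid with $\#\{T_r > q\}/R \le
\alpha$ - ties resolved toward the smaller threshold, i.e. toward
*attaining* the 5% level rather than undershooting it. Strong-control
calibration (`calibrate_strong()`) applies the same construction to the
null baskets of every scenario and takes the largest of the per-scenario
thresholds, using one common replicate set.

Two properties of this procedure deserve attention. First, the calibrated
threshold decreases with borrowing strength: under strong shrinkage the
per-basket exceedance probabilities are highly correlated under the global
null, so their maximum is stochastically smaller and a lower threshold
already controls the family-wise error. The package's calibrated values
(about 0.977 / 0.967 / 0.948 for no/moderate/strong borrowing at the
benchmark conditions) respect this ordering, and the test suite asserts
it. Second, under the no-borrowing prior the exceedance probability takes
only $n + 1$ distinct values, so $T_r$ is atomic and the calibrated
threshold can jump between atoms (about 0.977 and 0.994 here) when the
null tail frequency crosses $\alpha$ within Monte-Carlo noise; any
threshold between two atoms yields identical decisions, so this is a
presentation artifact of quantile reporting, not an instability of the
design.

## The MATS double-basket model

For phase I dose optimization, `fit_mats()` implements the multi-arm
two-stage structure: stage 1 expands the higher dose in $J$ indications;
indications where it looks promising at the interim are selected
($D_j = 1$) for a stage-2 randomized comparison of both doses. The model
borrows across indications through
$\gamma_{1j} = \mathrm{logit}(\pi_{1j}) - \mathrm{logit}(\pi_{0j}) \sim
N(\mu_1, \sigma_1^2)$ and the dose contrast
$\gamma_{2j} = \mathrm{logit}(\pi_{1j}) - \mathrm{logit}(\pi_{2j}) \sim
\mathrm{LogNormal}(\mu_2, \sigma_2^2)$, the latter encoding monotone
dose-response ($\pi_{1j} > \pi_{2j}$ with probability one a priori and a
posteriori); a sign-neutral normal alternative is available
(`neutral_gamma2`). The low-dose rate is derived, not separately
parameterized: $\mathrm{logit}(\pi_{2j}) = \mathrm{logit}(\pi_{1j}) -
\gamma_{2j}$, exactly as the transformation block implies, and indications
communicate only through the two population distributions. Hyperpriors
default to $N(0, 10^2)$ means and InvGamma(0.1, 0.1) variances - the
families are fixed by the design, the constants are package defaults and
configurable. The sampler mirrors the basket sampler (Metropolis on the
per-indication quantities, conjugate draws for all four hyperparameters).

The interim selection rule's threshold and timing are design
configuration, not model quantities; `simulate_mats()`'s default interim
uses an independent Beta(1,1) posterior per indication, a deterministic
function of the stage-1 count, so simulated selection frequencies can be
checked against exact enumeration. A hierarchical interim is a drop-in
replacement via `select_fun`. The reversed design (randomize first,
expand later) is a configuration of the same code, with stage roles
swapped.

## What the simulations do and do not show

The generator emulates exactly the benchmark conditions: fixed per-basket
sample sizes, independent binomial responses at constant true rates,
simultaneous analysis at full enrollment (or at fixed interim looks). It
does not emulate staggered accrual, response drift over time,
patient-level covariates, misclassified endpoints, or correlated outcomes
within centers - so passing operating-characteristic tests demonstrates
correctness of the methods under the stated sampling model, not robustness
of basket designs in messier trials. Reproduction of benchmark simulation
values is expected only to Monte-Carlo tolerance: the benchmark's own
tables carry standard errors near 1.5 percentage points at 1000
replicates, and the sampler behind them (iterations, software) is not
specified.

Problem sizes used by the test suite and the acceptance script - 1000
replicates per calibration and per operating-characteristic cell, 20
random data sets for the engine cross-check, 50 replicates for
hierarchical-mean recovery at $J = 8$, $n = 100$ - were chosen to keep
every Monte-Carlo standard error several times smaller than the tolerance
it is tested against.

## Known limitations

Partition averaging enumerates all set partitions and is limited to
$J \le 10$ (Bell numbers); Dirichlet-process and trans-dimensional
mixture extensions are out of scope, as are gradient-based samplers,
predictive-probability futility rules, covariate-conditional
exchangeability, and confirmatory-trial pruning designs. The quadrature
engine covers the independent and hierarchical normal models only; the
mixture, partition and indicator models rely on their own exact or MCMC
machinery.
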