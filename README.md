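# basketborrow

Bayesian information borrowing for basket trials.

A basket trial tests one therapy simultaneously in several disease cohorts
("baskets"), each a small single-arm study with a binary response endpoint:
`y_j | n_j, pi_j ~ Bin(n_j, pi_j)`, with efficacy in basket *j* declared
when `Pr(pi_j > pi0_j | data) > q_j` for a basket-specific reference rate
`pi0_j`. Because every basket receives the same drug, the basket effects can
be modeled as draws from a common population distribution,

```
gamma_j = h(pi_j),    gamma_j | theta ~ iid G(theta),
```

so that each basket's estimate is informed by the others (shrinkage). The
package is aimed at trial statisticians designing or analyzing exploratory
basket trials: it provides the transformations `h` (identity, logit,
logit-increment over the reference rate, hypothesis indicator), the prior
families `G` (independent wide normals; hierarchical normals with
half-normal, half-t or inverse-gamma hyperpriors; finite normal mixtures;
Bayesian model averaging over set partitions; Bernoulli/truncated-beta
hypothesis-level borrowing), posterior inference by adaptive MCMC and by a
deterministic quadrature engine, posterior-probability decision and interim
futility rules, exact Clopper-Pearson stratified analysis as the
no-borrowing comparator, a frequentist operating-characteristics simulator
with weak/strong family-wise error rate (FWER) calibration, and the
multi-arm two-stage (MATS) double-basket model for phase I dose
optimization.

## Worked example: borrowing vs stratified analysis

The bundled `imatinib` fixture holds a 10-basket advanced-sarcoma trial
(179 patients, reference rate 30%). Fit the moderate-borrowing hierarchical
model - `gamma_j = logit(pi_j) - logit(0.3)`, `gamma_j ~ N(mu, sigma^2)`,
`mu ~ N(0, 100^2)`, `sigma ~ Half-N(3)` - with the deterministic engine and
compare with the per-basket exact analysis:

```r
library(basketborrow)
im  <- basket_fixture("imatinib")
fit <- fit_oracle(named_prior("prior_II"), im)   # pi0 = 0.30 per basket
st  <- stratified_analysis(im)
round(pooled_rate(im), 3)
#> [1] 0.156
print(fit)
#> Posterior summary (oracle engine)
#>              basket prob_exceed post_mean_pi  ci_low ci_high
#> 1      Angiosarcoma   0.0079097       0.1499 0.05895  0.2486
#> 2             Ewing   0.0011116       0.1262 0.02533  0.2147
#> 3      Fibrosarcoma   0.0051801       0.1415 0.04469  0.2367
#> 4    Leiomyosarcoma   0.0193643       0.1735 0.09355  0.2812
#> 5       Liposarcoma   0.0327074       0.1831 0.10092  0.3007
#> 6               MFH   0.0008791       0.1387 0.05617  0.2185
#> 7      Osteosarcoma   0.0128042       0.1659 0.08572  0.2680
#> 8             MPNST   0.0301398       0.1605 0.05750  0.2956
#> 9  Rhabdomyosarcoma   0.0206838       0.1491 0.03776  0.2732
#> 10         Synovial   0.0071476       0.1533 0.06767  0.2491
```

Reading the output: `prob_exceed` is `Pr(pi_j > 0.30 | data)` - nowhere
near a 0.95-type threshold, reproducing the trial's negative conclusion;
`post_mean_pi` are the shrunken rate estimates, pulled from the raw `y_j /
n_j` toward the pooled rate 15.6% (e.g. the 0/13 Ewing basket moves from
0% to 12.6%); and every 95% credible interval is strictly narrower than
the corresponding Clopper-Pearson interval in `st` - the two baskets with
2-5 patients shrink the most. The same model fitted by MCMC
(`fit_basket(named_prior("prior_II"), im, mcmc_config(seed = 1))`) agrees
with the quadrature engine to well under 0.015 on every exceedance
probability.

Design evaluation uses the same machinery in simulation, e.g. calibrating
the decision threshold for 5% FWER under a 4-basket global null and then
measuring power:

```r
null_sc <- basket_fixture("scenarios")[[1]]     # all true rates = pi0 = 0.2
des <- design_spec(named_prior("prior_III"), NULL, n_per_basket = 20)
cal <- calibrate_weak(des, null_sc, alpha = 0.05, reps = 1000, seed = 1)
cal$q
#> [1] 0.948
alt <- basket_fixture("scenarios")[[2]]         # all true rates = 0.35
operating_characteristics(design_spec(named_prior("prior_III"),
                                      decision_rule(cal$q), 20),
                          alt, reps = 1000, seed = 2)
#> Operating characteristics, scenario 'global alternative' (1000 replicates)
#>   reject %: 83.0  81.6  81.4  81.7
#>   FWP-D: 94.0%  FWP-C: 64.5%
```

A command-line wrapper over the same functions ships in
`inst/cli/basketborrow.R` (subcommands `analyze`, `calibrate`, `oc`,
`mats-fit`, `mats-sim`, driven by a YAML config; see `?basket_cli`).

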