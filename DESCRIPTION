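Package: basketborrow
Title: Bayesian Information Borrowing for Basket Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design and analysis machinery for phase II basket trials with
    Bayesian information borrowing across baskets. Implements transformations
    of binomial response rates (identity, logit, logit increment from a
    reference rate, and hypothesis-level indicators), exchangeable priors
    (independent wide normals, hierarchical normals with half-normal, half-t
    or inverse-gamma hyperpriors, finite normal mixtures, Bayesian model
    averaging over set partitions, and Bernoulli/truncated-beta hypothesis
    borrowing), posterior inference by adaptive Metropolis-within-Gibbs MCMC
    and by a deterministic nested-quadrature engine, posterior-probability
    efficacy decisions, exact Clopper-Pearson stratified analysis, interim
    futility rules, and a frequentist operating-characteristics simulator
    with weak and strong family-wise error rate threshold calibration.
    Also provides the multi-arm two-stage (MATS) double-basket model for
    phase I dose optimization across doses and indications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
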