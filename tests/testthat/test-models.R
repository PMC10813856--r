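test_that("the three benchmark priors are assembled as specified", {
  m1 <- named_prior("prior_I")
  expect_equal(m1$transform$kind, "logit_increment")
  expect_equal(m1$prior$family, "independent_normal")
  expect_equal(m1$prior$sd, 100)
  m2 <- named_prior("prior_II")
  expect_equal(m2$prior$sigma_prior$kind, "half_normal")
  expect_equal(m2$prior$sigma_prior$A, 3)
  expect_equal(m2$prior$mu_sd, 100)
  m3 <- named_prior("prior_III")
  expect_equal(m3$prior$sigma_prior$A, 0.3)
  expect_error(named_prior("prior_IV"), "valid names")
  expect_error(model_spec(transform_spec("hypothesis_indicator"), hier_normal()),
               "must be used together")
})

test_that("gamma log densities match closed-form values", {
  expect_equal(log_density_gamma(hier_normal(), 0, list(mu = 0, sigma = 1)),
               -0.5 * log(2 * pi))
  # one-component mixture reduces to the plain hierarchical density
  set.seed(3)
  g <- rnorm(100)
  mix1 <- mixture_normal(1)
  for (i in seq(1, 100, by = 20)) {
    expect_equal(
      log_density_gamma(mix1, g[i], list(mu = 0.4, sigma = 1.3, w = 1)),
      log_density_gamma(hier_normal(), g[i], list(mu = 0.4, sigma = 1.3)))
  }
  # two equal-weight components: log of the average density
  mix2 <- mixture_normal(2)
  expect_equal(
    log_density_gamma(mix2, 0, list(mu = c(-1, 1), sigma = c(1, 1),
                                    w = c(0.5, 0.5))),
    log((dnorm(0, -1, 1) + dnorm(0, 1, 1)) / 2))
  expect_error(log_density_gamma(hier_normal(), Inf, list(mu = 0, sigma = 1)),
               "finite")
})

test_that("hyperprior densities match their closed forms and supports", {
  # half-normal mode value
  expect_equal(log_hyperprior(hier_normal(sigma_prior = half_normal(3)),
                              list(mu = 0, sigma = 0)),
               dnorm(0, 0, 100, log = TRUE) + log(2 / (3 * sqrt(2 * pi))))
  # half-t with one degree of freedom is half-Cauchy
  A <- 2.5
  sig <- seq(0, 10, by = 0.5)
  ht <- basketborrow:::.log_sigma_density(half_t(1, A), sig)
  hc <- log(2 / (pi * A * (1 + (sig / A)^2)))
  expect_equal(ht, hc, tolerance = 1e-12)
  # out of support
  for (sp in list(half_normal(1), half_t(3, 1), inv_gamma(2, 2), fixed_sigma(1)))
    expect_identical(log_hyperprior(hier_normal(sigma_prior = sp),
                                    list(mu = 0, sigma = -1)), -Inf)
})

test_that("every prior family implies an exchangeable joint density", {
  set.seed(11)
  g <- rnorm(6)
  cases <- list(
    list(p = independent_normal(0.3, 2), th = NULL),
    list(p = hier_normal(), th = list(mu = 0.5, sigma = 1.2)),
    list(p = mixture_normal(2), th = list(mu = c(-1, 1), sigma = c(1, 2),
                                          w = c(0.3, 0.7))))
  for (cs in cases) {
    base <- log_density_gamma(cs$p, g, cs$th)
    for (r in 1:5) {
      expect_equal(log_density_gamma(cs$p, g[sample(6)], cs$th), base)
    }
  }
  gi <- c(1, 0, 1, 1, 0)
  base <- log_density_gamma(indicator_borrow(), gi, list(rho = 0.4))
  expect_equal(log_density_gamma(indicator_borrow(), rev(gi), list(rho = 0.4)),
               base)
})

test_that("hierarchical priors induce positive a-priori correlation", {
  set.seed(21)
  M <- 4000
  sig <- abs(rnorm(M, 0, 1))
  mu <- rnorm(M, 0, 2)
  g1 <- rnorm(M, mu, sig); g2 <- rnorm(M, mu, sig)
  expect_gt(cor(g1, g2), 0.5)
})

test_that("model specifications survive serialization", {
  for (m in list(named_prior("prior_II"),
                 model_spec(transform_spec("logit"), mixture_normal(2, 0.5)),
                 model_spec(transform_spec("logit_increment"),
                            partition_bma(0, 1.5, lambda = 0.2)),
                 model_spec(transform_spec("hypothesis_indicator"),
                            indicator_borrow(c(2, 1))))) {
    back <- model_from_list(model_to_list(m))
    expect_equal(back, m)
  }
})
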