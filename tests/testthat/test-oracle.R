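# the deterministic quadrature engine, cross-checked against independent
# one-dimensional integration (stats::integrate) and structural symmetries

test_that("the no-pooling model factorizes: engine matches independent 1-D integrals", {
  d <- toy_data(y = c(2, 6, 5, 8))
  fit <- fit_oracle(named_prior("prior_I"), d)
  off <- qlogis(0.2)
  pe_ref <- vapply(seq_along(d$y), function(j) {
    f <- function(g) dbinom(d$y[j], d$n[j], plogis(g + off)) * dnorm(g, 0, 100)
    up <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
    up / (up + integrate(f, -Inf, 0, rel.tol = 1e-10)$value)
  }, numeric(1))
  expect_equal(fit$prob_exceed, pe_ref, tolerance = 1e-6)
  # removing a basket leaves the others untouched (single-arm behavior)
  d3 <- basket_data(NULL, d$y[-2], d$n[-2], 0.2)
  fit3 <- fit_oracle(named_prior("prior_I"), d3)
  expect_equal(fit3$prob_exceed, fit$prob_exceed[-2], tolerance = 1e-9)
})

test_that("hierarchical engine matches a brute-force nested integration", {
  d <- basket_data(NULL, y = c(6, 2), n = c(20, 20), pi0 = 0.2)
  fit <- fit_oracle(named_prior("prior_II"), d)
  # independent brute force: coarse but unbiased 2-D Riemann sum with
  # stats::integrate inner integrals
  off <- qlogis(0.2)
  inner <- function(mu, s, y, lo, hi)
    integrate(function(g) dbinom(y, 20, plogis(g + off)) * dnorm(g, mu, s),
              lo, hi, rel.tol = 1e-9, stop.on.error = FALSE)$value
  mus <- seq(-8, 8, length.out = 161)
  lss <- seq(log(0.01), log(40), length.out = 121)
  tot <- num <- 0
  for (ls in lss) {
    s <- exp(ls)
    pw <- dnorm(mus, 0, 100) * (2 * dnorm(s, 0, 3)) * s
    L1a <- vapply(mus, function(m) inner(m, s, 6, -50, 0), numeric(1))
    L1b <- vapply(mus, function(m) inner(m, s, 6, 0, 50), numeric(1))
    L2 <- vapply(mus, function(m) inner(m, s, 2, -50, 50), numeric(1))
    tot <- tot + sum(pw * (L1a + L1b) * L2)
    num <- num + sum(pw * L1b * L2)
  }
  expect_equal(fit$prob_exceed[1], num / tot, tolerance = 5e-3)
})

test_that("symmetric data give identical exceedance probabilities", {
  d <- toy_data(y = c(2, 2, 2, 2))
  fit <- fit_oracle(named_prior("prior_II"), d)
  expect_lt(diff(range(fit$prob_exceed)), 1e-10)
  expect_lt(diff(range(fit$post_mean_pi)), 1e-8)
})

test_that("exceedance probability is non-decreasing in the observed count", {
  cells <- basketborrow:::.prior_cells(named_prior("prior_II")$prior, grid_config())
  pe <- basketborrow:::.exceed_matrix(named_prior("prior_II"),
                                      cbind(0:20, 5), c(20, 20), 0.2, 0, grid_config())
  expect_true(all(diff(pe[, 1]) > 0))
  # and for the no-pooling model
  peI <- basketborrow:::.exceed_matrix(named_prior("prior_I"),
                                       cbind(0:20, 5), c(20, 20), 0.2, 0, grid_config())
  expect_true(all(diff(peI[, 1]) > 0))
})

test_that("credible intervals are ordered and contain the posterior mass", {
  fit <- fit_oracle(named_prior("prior_II"), toy_data())
  expect_true(all(fit$ci_low <= fit$ci_high))
  expect_true(all(fit$prob_exceed >= 0 & fit$prob_exceed <= 1))
  expect_true(all(fit$post_mean_pi > 0 & fit$post_mean_pi < 1))
})
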