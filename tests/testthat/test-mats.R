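test_that("the dose-indication transformations evaluate as displayed", {
  tr <- mats_transform(0.35, 0.20, 0.20)
  expect_equal(tr$gamma1, qlogis(0.35) - qlogis(0.20))
  expect_equal(tr$gamma2, qlogis(0.35) - qlogis(0.20))
  expect_equal(mats_transform(0.3, 0.3, 0.3), list(gamma1 = 0, gamma2 = 0))
  expect_gt(mats_transform(0.4, 0.25, 0.2)$gamma2, 0)
  expect_error(mats_transform(1, 0.2, 0.2), "strictly inside")
})

test_that("data container enforces the two-stage structure", {
  arms <- data.frame(dose = c(1, 1, 2), indication = c(1, 1, 1),
                     stage = c(1, 2, 2), y = c(5, 6, 3), n = c(20, 20, 20))
  md <- mats_data(arms, pi0 = 0.2)
  expect_true(md$D[1])
  expect_error(mats_data(data.frame(dose = 2, indication = 1, stage = 1,
                                    y = 1, n = 10), 0.2),
               "stage 1 enrolls only the higher dose")
  expect_error(mats_data(data.frame(dose = 1, indication = 1, stage = 1,
                                    y = 11, n = 10), 0.2), "y <= n")
  # round-trip through the long CSV format
  p <- withr::local_tempfile(fileext = ".csv")
  write_mats(md, p)
  back <- load_mats(p, 0.2)
  expect_equal(back$y, md$y)
  expect_equal(back$D, md$D)
})

test_that("selection thresholds behave at the extremes", {
  expect_true(all(mats_select(c(0.1, 0.5, 0.9), 0)))
  expect_equal(mats_select(c(0.9, 0.3, 0.7), 0.5), c(TRUE, FALSE, TRUE))
  expect_false(any(mats_select(c(0.3, 0.99), 1)))
})

test_that("simulated trials follow the selection-gated sampling scheme", {
  sm <- simulate_mats(rep(1, 3), rep(1, 3), 0.2, 20, 15, threshold = 0.9, seed = 4)
  expect_true(all(sm$D))
  expect_true(all(sm$y[!is.na(sm$n)] == sm$n[!is.na(sm$n)]))
  # an unattainable threshold generates no stage-2 data
  sm0 <- simulate_mats(rep(0.5, 3), rep(0.4, 3), 0.2, 20, 15, threshold = 1, seed = 4)
  expect_false(any(sm0$D))
  expect_true(all(is.na(sm0$n[, , 2])))

  # selection frequency matches exact enumeration of the interim rule
  pe_y <- 1 - pbeta(0.2, 0:20 + 1, 20 - 0:20 + 1)
  p_exact <- sum(dbinom(0:20, 20, 0.35)[pe_y >= 0.5])
  sel <- vapply(1:5000, function(s)
    simulate_mats(0.35, 0.2, 0.2, 20, 10, 0.5, seed = s)$D, logical(1))
  se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(mean(sel) - p_exact), 3 * se)
})

test_that("the hierarchical fit respects the dose-ordering assumption", {
  arms <- data.frame(dose = c(1, 1, 1, 1, 2, 1, 2),
                     indication = c(1, 2, 3, 1, 1, 2, 2),
                     stage = c(1, 1, 1, 2, 2, 2, 2),
                     y = c(7, 7, 7, 8, 4, 8, 4), n = rep(20, 7))
  md <- mats_data(arms, pi0 = 0.2)
  f <- fit_mats(md, mats_prior(), quick_mcmc(3, chains = 2, iterations = 4000))
  expect_true(all(attr(f, "draws")$gamma2 >= 0))
  expect_true(all(f$pr_pi1_gt_pi2 >= 0.999))
  # symmetric indications 1 and 2 get equal summaries within MC error
  expect_lt(abs(f$pr_pi1_gt_pi0[1] - f$pr_pi1_gt_pi0[2]), 0.03)
  expect_lt(abs(f$pi1_mean[1] - f$pi1_mean[2]), 0.02)

  # with the sign-neutral contrast prior and identical dose arms, neither
  # dose is favored
  arms_eq <- data.frame(dose = c(1, 1, 2), indication = c(1, 1, 1),
                        stage = c(1, 2, 2), y = c(6, 6, 6), n = rep(20, 3))
  fn <- fit_mats(mats_data(arms_eq, 0.2), mats_prior(neutral_gamma2 = TRUE),
                 quick_mcmc(5, chains = 2, iterations = 4000))
  expect_lt(abs(fn$pr_pi1_gt_pi2[1] - 0.5), 0.08)

  expect_error(fit_mats(mats_data(arms, 0.2, selected = c(TRUE, TRUE, TRUE)),
                        mats_prior(), quick_mcmc(1)),
               "no stage-2 data")
})

test_that("a single indication with tight hyperpriors reduces to one basket", {
  arms <- data.frame(dose = 1, indication = 1, stage = 1, y = 9, n = 20)
  md <- mats_data(arms, pi0 = 0.2)
  # sigma^2 ~ InvGamma(200, 199) concentrates near 1; marginally
  # gamma1 ~ N(0, s1^2 + 1) to good approximation
  pr <- mats_prior(m1 = 0, s1 = 2, a1 = 200, b1 = 199)
  f <- fit_mats(md, pr, quick_mcmc(6, chains = 2, iterations = 6000))
  ref <- fit_oracle(model_spec(transform_spec("logit_increment"),
                               independent_normal(0, sqrt(4 + 1))),
                    basket_data(NULL, 9, 20, 0.2))
  expect_lt(abs(f$pr_pi1_gt_pi0[1] - ref$prob_exceed[1]), 0.02)
})

test_that("a strongly positive companion indication lifts the posterior", {
  arms1 <- data.frame(dose = 1, indication = 1, stage = 1, y = 6, n = 20)
  f1 <- fit_mats(mats_data(arms1, 0.2), mats_prior(),
                 quick_mcmc(7, chains = 2, iterations = 6000))
  arms2 <- data.frame(dose = c(1, 1), indication = c(1, 2), stage = c(1, 1),
                      y = c(6, 14), n = c(20, 20))
  f2 <- fit_mats(mats_data(arms2, 0.2), mats_prior(),
                 quick_mcmc(7, chains = 2, iterations = 6000))
  expect_gt(f2$pr_pi1_gt_pi0[1], f1$pr_pi1_gt_pi0[1] - 0.02)
  expect_gt(f2$pr_pi1_gt_pi0[1], f1$pr_pi1_gt_pi0[1])
})
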