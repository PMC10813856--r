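test_that("trial simulation draws binomial responses with the right moments", {
  s1 <- scenario("all", rep(1, 3), 0.2)
  expect_equal(simulate_trial(s1, 20, 1)$y, rep(20L, 3))
  s0 <- scenario("none", rep(0, 3), 0.2)
  expect_equal(simulate_trial(s0, 20, 1)$y, rep(0L, 3))

  sc <- scenario("null", rep(0.2, 4), 0.2)
  ys <- vapply(1:2500, function(s) simulate_trial(sc, 20, s)$y, integer(4))
  m <- mean(ys)                       # 10,000 binomial draws
  se <- sqrt(20 * 0.2 * 0.8 / length(ys))
  expect_lt(abs(m - 4), 3 * se)
  d <- simulate_trial(sc, 20, 5)
  expect_equal(d$pi0, sc$pi0)
})

test_that("power and error summaries obey their structural orderings", {
  sc <- scenario("mixed", c(0.2, 0.35, 0.35, 0.35), 0.2)
  des <- design_spec(named_prior("prior_I"), decision_rule(0.9), 20)
  res <- operating_characteristics(des, sc, reps = 500, seed = 3)
  prom <- sc$promising
  expect_lte(res$FWP_C, min(res$reject_pct[prom]) + 1e-9)
  expect_gte(res$FWP_D, max(res$reject_pct[prom]) - 1e-9)
  expect_gte(res$FWER, max(res$reject_pct[!prom]) - 1e-9)
  expect_true(all(res$reject_pct >= 0 & res$reject_pct <= 100))
  expect_true(all(is.finite(res$reject_se)))

  # no null basket: FWER undefined; no promising basket: powers undefined
  res2 <- operating_characteristics(des, scenario("alt", rep(0.35, 4), 0.2),
                                    reps = 200, seed = 3)
  expect_true(is.na(res2$FWER))
  res3 <- operating_characteristics(des, scenario("null", rep(0.2, 4), 0.2),
                                    reps = 200, seed = 3)
  expect_true(is.na(res3$FWP_D))
  # an unattainable threshold never rejects
  des0 <- design_spec(named_prior("prior_I"), decision_rule(0.999999), 20)
  expect_equal(operating_characteristics(des0, res3_sc <- scenario("null", rep(0.2, 4), 0.2),
                                         reps = 200, seed = 3)$FWER, 0)
})

test_that("empirical FWER is non-increasing in the threshold under CRN", {
  sc <- scenario("null", rep(0.2, 4), 0.2)
  qs <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  fwer <- vapply(qs, function(q) {
    des <- design_spec(named_prior("prior_II"), decision_rule(q), 20)
    operating_characteristics(des, sc, reps = 300, seed = 11)$FWER
  }, numeric(1))
  expect_true(all(diff(fwer) <= 0))
})

test_that("weak calibration attains its target level on fresh replicates", {
  des <- design_spec(named_prior("prior_III"), NULL, 20)
  cal <- calibrate_weak(des, bb_null, alpha = 0.05, reps = 1000, seed = 21)
  expect_true(cal$q > 0.8 && cal$q < 1)
  expect_lte(cal$achieved_fwer, 0.05)
  fresh <- operating_characteristics(
    design_spec(named_prior("prior_III"), decision_rule(cal$q), 20),
    bb_null, reps = 1000, seed = 22)
  expect_lt(abs(fresh$FWER - 5), 2)

  expect_error(calibrate_weak(des, bb_scenarios[[2]], seed = 1),
               "global null")
  # degenerate level: any rejection rate is allowed
  cal1 <- calibrate_weak(des, bb_null, alpha = 1, reps = 100, seed = 1)
  expect_equal(cal1$q, 0)
})

test_that("strong calibration reduces to weak on a single global null", {
  desI <- design_spec(named_prior("prior_I"), NULL, 20)
  w <- calibrate_weak(desI, bb_null, reps = 400, seed = 9)
  s <- calibrate_strong(desI, list(bb_null), reps = 400, seed = 9)
  expect_equal(s$q, w$q)
  expect_error(calibrate_strong(desI, list(bb_scenarios[[2]]), reps = 50, seed = 1),
               "no scenario contains a null basket")
})

test_that("interim futility saves patients without inflating the error rate", {
  ir <- interim_rule(midpoint_reference(0.2, 0.35), c = 0.1, looks = 10)
  des_int <- design_spec(named_prior("prior_II"), decision_rule(0.95), 20, ir)
  des_fix <- design_spec(named_prior("prior_II"), decision_rule(0.95), 20)
  r_int <- operating_characteristics(des_int, bb_null, reps = 2000, seed = 31)
  r_fix <- operating_characteristics(des_fix, bb_null, reps = 2000, seed = 31)
  expect_true(all(r_int$expected_n <= 20))
  expect_true(any(r_int$expected_n < 20))   # stopping actually occurs
  margin <- 2 * sqrt(r_int$FWER_se^2 + r_fix$FWER_se^2)
  expect_lte(r_int$FWER, r_fix$FWER + margin)
  # under the alternative, power is reduced, not increased
  r_int2 <- operating_characteristics(des_int, bb_scenarios[[2]], reps = 500, seed = 32)
  r_fix2 <- operating_characteristics(des_fix, bb_scenarios[[2]], reps = 500, seed = 32)
  m2 <- 2 * sqrt(r_int2$FWP_D_se^2 + r_fix2$FWP_D_se^2)
  expect_lte(r_int2$FWP_D, r_fix2$FWP_D + m2)
})

test_that("the table layout is one row per scenario and variant", {
  variants <- list(no = design_spec(named_prior("prior_I"), decision_rule(0.98), 20),
                   strong = design_spec(named_prior("prior_III"), decision_rule(0.95), 20))
  tab <- oc_table(variants, bb_scenarios[1:2], reps = 100, seed = 2)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("scenario", "borrowing", "reject_pct_1", "FWER",
                    "FWP_D", "FWP_C") %in% names(tab)))
  tab2 <- oc_table(variants, bb_scenarios[1:2], reps = 100, seed = 2)
  expect_identical(tab$FWER, tab2$FWER)  # same seed, same table
})
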