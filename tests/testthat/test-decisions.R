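test_that("the rejection rule uses a strict inequality and is monotone in q", {
  expect_false(decide(0.95, decision_rule(0.95)))
  expect_equal(decide(c(0.99, 0.50), decision_rule(0.982)), c(TRUE, FALSE))
  expect_false(any(decide(rep(0, 4), decision_rule(0.5))))
  pe <- c(0.2, 0.8, 0.95, 0.999)
  qs <- seq(0.05, 0.95, by = 0.05)
  rej <- vapply(qs, function(q) sum(decide(pe, decision_rule(q))), numeric(1))
  expect_true(all(diff(rej) <= 0))
  expect_error(decision_rule(1.2), "strictly in")
})

test_that("Clopper-Pearson endpoints invert the exact binomial tails", {
  expect_equal(unname(clopper_pearson(0, 13)[1]), 0)
  expect_equal(unname(clopper_pearson(13, 13)[2]), 1)
  ci <- clopper_pearson(28, 179)
  expect_true(ci[1] < 28 / 179 && 28 / 179 < ci[2])
  expect_error(clopper_pearson(2, 0), "degenerate")

  # independent oracle: root-find the tail equations
  # P(X >= y | L) = alpha/2 and P(X <= y | U) = alpha/2
  for (case in list(c(2, 15), c(5, 26), c(1, 5))) {
    y <- case[1]; n <- case[2]
    ci <- clopper_pearson(y, n, 0.95)
    L <- uniroot(function(p) 1 - pbinom(y - 1, n, p) - 0.025,
                 c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    U <- uniroot(function(p) pbinom(y, n, p) - 0.025,
                 c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(unname(ci[1]), L, tolerance = 1e-8)
    expect_equal(unname(ci[2]), U, tolerance = 1e-8)
  }
})

test_that("exact intervals achieve nominal coverage for every rate (n <= 30)", {
  for (n in c(1:10, 15, 20, 25, 30)) {
    ci <- clopper_pearson(0:n, n, 0.95)
    for (p in seq(0.005, 0.995, length.out = 67)) {
      cover <- sum(dbinom(0:n, n, p)[ci[, 1] <= p & p <= ci[, 2]])
      expect_gte(cover, 0.95 - 1e-12)
    }
  }
})

test_that("stratified analysis is per-basket and permutation-equivariant", {
  im <- basket_fixture("imatinib")
  st <- stratified_analysis(im)
  expect_equal(st$estimate[1], 2 / 15, tolerance = 1e-12)
  expect_equal(st$estimate[2], 0)
  perm <- c(3, 1, 2, 10, 4:9)
  imp <- basket_data(im$labels[perm], im$y[perm], im$n[perm], im$pi0[perm])
  stp <- stratified_analysis(imp)
  expect_equal(stp$estimate, st$estimate[perm])
  expect_equal(stp$ci_high, st$ci_high[perm])
})

test_that("futility reference and interim rule follow their definitions", {
  expect_equal(midpoint_reference(0.2, 0.4), 0.3)
  expect_equal(midpoint_reference(0.15, 0.35), 0.25)
  expect_error(midpoint_reference(0.3, 0.3), "pi0 < pi1")

  ir <- interim_rule(0.3, c = 0.05, looks = 10)
  expect_true(futility_check(0.04, ir, 1))
  expect_false(futility_check(0.05, ir, 1))   # strict inequality
  ir0 <- interim_rule(0.3, c = 0, looks = 10)
  expect_false(any(futility_check(c(0, 0.5, 1), ir0, 1)))
  expect_error(futility_check(0.5, ir, 2), "schedule")
  expect_error(interim_rule(0.3, 0.05, looks = c(10, 10)), "increasing")
})
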