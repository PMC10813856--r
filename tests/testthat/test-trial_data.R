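test_that("bundled fixtures carry the published trial counts", {
  im <- basket_fixture("imatinib")
  expect_s3_class(im, "basket_data")
  expect_length(im$y, 10)
  expect_equal(im$y, c(2L, 0L, 1L, 6L, 7L, 3L, 5L, 1L, 0L, 3L))
  expect_equal(im$n, c(15L, 13L, 12L, 28L, 29L, 29L, 26L, 5L, 2L, 20L))
  expect_equal(sum(im$n), 179L)
  expect_true(all(im$pi0 == 0.30))

  ve <- basket_fixture("vemurafenib")
  expect_equal(ve$y, c(2L, 6L, 1L, 1L, 0L, 8L))
  expect_equal(ve$n, c(7L, 14L, 8L, 26L, 10L, 19L))
  expect_true(all(ve$pi0 == 0.15))

  scn <- basket_fixture("scenarios")
  expect_length(scn, 6)
  expect_true(all(scn[[1]]$pi_true == 0.20))
  expect_false(any(scn[[1]]$promising))
  expect_true(all(scn[[2]]$promising))
  expect_equal(scn[[5]]$pi_true, c(0.10, 0.20, 0.30, 0.40))
  expect_equal(scn[[3]]$promising, c(FALSE, TRUE, TRUE, TRUE))

  expect_error(basket_fixture("nope"), "valid names")
})

test_that("validation rejects impossible rows and names the offender", {
  expect_error(basket_data(NULL, y = 5, n = 3, pi0 = 0.5), "y <= n")
  expect_error(basket_data(NULL, y = c(1, 2), n = c(5, 5), pi0 = c(0.2, 1.2)),
               "row 2")
  expect_error(basket_data(NULL, y = 1, n = 5, pi0 = 0.2, pi1 = 0.1),
               "pi0 < pi1")
  d <- basket_data(NULL, y = 0, n = 1, pi0 = 0.5)
  expect_length(d$y, 1)
})

test_that("CSV loading validates columns and round-trips integer fields", {
  p <- withr::local_tempfile(fileext = ".csv")
  im <- basket_fixture("imatinib")
  write_trial(im, p)
  back <- load_trial(p)
  expect_identical(back$y, im$y)
  expect_identical(back$n, im$n)
  expect_identical(back$labels, im$labels)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("basket,y,n\nA,1,5", bad)
  expect_error(load_trial(bad), "pi0")
  expect_error(load_trial("no/such/file.csv"), "not found")
})

test_that("pooled rate is a count ratio, permutation- and merge-invariant", {
  expect_equal(pooled_rate(basket_fixture("imatinib")), 28 / 179)
  expect_equal(pooled_rate(basket_fixture("vemurafenib")), 18 / 84)
  expect_equal(pooled_rate(basket_data(NULL, c(0, 0), c(5, 5), 0.2)), 0)

  set.seed(1)
  d <- toy_data()
  perm <- sample(4)
  dp <- basket_data(NULL, d$y[perm], d$n[perm], d$pi0[perm])
  expect_equal(pooled_rate(dp), pooled_rate(d))
  merged <- basket_data(NULL, c(d$y[1] + d$y[2], d$y[3:4]),
                        c(d$n[1] + d$n[2], d$n[3:4]), 0.2)
  expect_equal(pooled_rate(merged), pooled_rate(d))
})

test_that("scenario flags promising baskets consistently with the rates", {
  s <- scenario("mixed", c(0.1, 0.2, 0.35), 0.2)
  expect_equal(s$promising, c(FALSE, FALSE, TRUE))
  expect_error(scenario("bad", c(0.2, 1.5), 0.2), "pi_true")
})
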