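# Bell-triangle recurrence, written independently of the package internals
bell_triangle <- function(J) {
  row <- 1
  for (i in seq_len(J - 1)) {
    new <- numeric(i + 1); new[1] <- row[length(row)]
    for (k in seq_len(i)) new[k + 1] <- new[k] + row[k]
    row <- new
  }
  row[length(row)]
}

canon <- function(p) {
  s <- lapply(p, sort)
  s[order(vapply(s, min, numeric(1)))]
}

test_that("partition enumeration lists every set partition exactly once", {
  p3 <- enumerate_partitions(3)
  expect_length(p3, 5)
  expected <- list(list(c(1, 2, 3)),
                   list(c(1, 2), 3),
                   list(c(1, 3), 2),
                   list(1, c(2, 3)),
                   list(1, 2, 3))
  got <- lapply(p3, canon)
  want <- lapply(expected, canon)
  for (w in want)
    expect_true(any(vapply(got, identical,
                           logical(1), lapply(w, as.integer))))
  expect_length(enumerate_partitions(1), 1)
  for (J in 1:8)
    expect_equal(length(enumerate_partitions(J)), bell_triangle(J))
  expect_error(enumerate_partitions(0), "between 1 and 12")
  expect_error(enumerate_partitions(13), "between 1 and 12")
})

test_that("partition averaging: weights normalize and data drive pooling", {
  m <- model_spec(transform_spec("logit_increment"), partition_bma())
  # single basket: one partition with all the weight
  f1 <- fit_bma(basket_data(NULL, 3, 20, 0.2), m)
  expect_equal(nrow(f1$partition_weights), 1)
  expect_equal(f1$partition_weights$posterior_weight, 1)

  # two identical baskets: the pooled partition gains weight over its prior
  # exactly when its marginal likelihood is larger; both marginals checked
  # against independent integration
  d <- basket_data(NULL, y = c(6, 6), n = c(20, 20), pi0 = 0.2)
  f2 <- fit_bma(d, m)
  expect_equal(sum(f2$partition_weights$posterior_weight), 1, tolerance = 1e-12)
  off <- qlogis(0.2)
  sd0 <- m$prior$within_sd
  ml_pooled <- integrate(function(g)
    dbinom(6, 20, plogis(g + off))^2 * dnorm(g, 0, sd0), -30, 30,
    rel.tol = 1e-10)$value
  ml_split1 <- integrate(function(g)
    dbinom(6, 20, plogis(g + off)) * dnorm(g, 0, sd0), -30, 30,
    rel.tol = 1e-10)$value
  expect_gt(ml_pooled, ml_split1^2)  # pooling favored for identical data
  w <- f2$partition_weights
  pooled_row <- which(w$n_subsets == 1)
  expect_gt(w$posterior_weight[pooled_row], w$prior_weight[pooled_row])
  # posterior weights agree with the independent marginal-likelihood ratio
  expect_equal(w$posterior_weight[pooled_row],
               ml_pooled / (ml_pooled + ml_split1^2), tolerance = 1e-6)

  expect_error(fit_bma(basket_data(NULL, rep(1, 11), rep(5, 11), 0.2), m),
               "J <= 10")
})

test_that("partition-size tilt shifts prior weight as configured", {
  d <- basket_data(NULL, y = c(5, 6, 2), n = rep(20, 3), pi0 = 0.2)
  f_flat <- fit_bma(d, model_spec(transform_spec("logit_increment"),
                                  partition_bma(lambda = 0)))
  f_tilt <- fit_bma(d, model_spec(transform_spec("logit_increment"),
                                  partition_bma(lambda = 2)))
  pw_flat <- f_flat$partition_weights
  pw_tilt <- f_tilt$partition_weights
  expect_true(all(pw_flat$prior_weight == pw_flat$prior_weight[1]))
  expect_lt(pw_tilt$prior_weight[pw_tilt$n_subsets == 3][1],
            pw_tilt$prior_weight[pw_tilt$n_subsets == 1][1])
})
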