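# Hypothesis-level borrowing: gamma_j = 1(pi_j > pi0_j) with a
# Beta-Bernoulli prior on the shared success probability and conditional
# truncated-beta priors for the rate on either side of the reference rate.
# The per-basket marginal likelihood given gamma_j is available in closed
# form through incomplete beta functions, so the posterior over the binary
# hypothesis vector is computed exactly by 2^J enumeration for J <= 12 and
# by Gibbs sampling beyond that.

# log marginal likelihood of (y, n) under a Beta(a, b) prior truncated to
# [lo, hi]
.log_trunc_beta_marg <- function(y, n, a, b, lo, hi) {
  num <- stats::pbeta(hi, y + a, n - y + b) - stats::pbeta(lo, y + a, n - y + b)
  den <- stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)
  if (den <= 0) return(-Inf)
  if (num <= 0) return(-Inf)
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b) + log(num) - log(den)
}

# mean of a Beta(a, b) truncated to [lo, hi]
.trunc_beta_mean <- function(a, b, lo, hi) {
  den <- stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)
  num <- stats::pbeta(hi, a + 1, b) - stats::pbeta(lo, a + 1, b)
  if (den <= 0) return((lo + hi) / 2)
  a / (a + b) * num / den
}

.trunc_beta_quantile <- function(p, a, b, lo, hi) {
  plo <- stats::pbeta(lo, a, b); phi <- stats::pbeta(hi, a, b)
  if (phi - plo <= 0) return(lo)
  stats::qbeta(plo + p * (phi - plo), a, b)
}

# posterior over the binary hypothesis vector; exact for J <= 12
fit_indicator <- function(model, data, config = NULL) {
  prior <- model$prior
  stopifnot(prior$family == "indicator_borrow")
  J <- length(data$y)
  a0 <- prior$prob_prior[1]; b0 <- prior$prob_prior[2]

  # per-basket log marginal likelihood under gamma_j = 0 / 1
  logm <- matrix(0, J, 2)
  for (j in seq_len(J)) {
    logm[j, 1] <- .log_trunc_beta_marg(data$y[j], data$n[j],
                                       prior$beta_low[1], prior$beta_low[2],
                                       0, data$pi0[j])
    logm[j, 2] <- .log_trunc_beta_marg(data$y[j], data$n[j],
                                       prior$beta_high[1], prior$beta_high[2],
                                       data$pi0[j], 1)
  }

  if (J <= 12) {
    G <- as.matrix(expand.grid(rep(list(0:1), J)))
    t_ <- rowSums(G)
    lp <- lbeta(a0 + t_, b0 + J - t_) - lbeta(a0, b0) +
      as.vector(G %*% logm[, 2] + (1 - G) %*% logm[, 1])
    w <- exp(lp - max(lp)); w <- w / sum(w)
    p1 <- as.vector(crossprod(G, w))
    method <- "exact"
  } else {
    if (is.null(config)) stop("J > 12 requires an mcmc_config for Gibbs sampling")
    p1 <- .indicator_gibbs(logm, a0, b0, config)
    method <- "mcmc"
  }

  # rate summaries: two-piece mixture of truncated-beta posteriors
  post_mean_pi <- ci_low <- ci_high <- numeric(J)
  for (j in seq_len(J)) {
    aL <- data$y[j] + prior$beta_low[1]; bL <- data$n[j] - data$y[j] + prior$beta_low[2]
    aH <- data$y[j] + prior$beta_high[1]; bH <- data$n[j] - data$y[j] + prior$beta_high[2]
    p0 <- 1 - p1[j]
    post_mean_pi[j] <- p0 * .trunc_beta_mean(aL, bL, 0, data$pi0[j]) +
      p1[j] * .trunc_beta_mean(aH, bH, data$pi0[j], 1)
    qfun <- function(p) {
      if (p0 > 0 && p <= p0)
        .trunc_beta_quantile(p / p0, aL, bL, 0, data$pi0[j])
      else
        .trunc_beta_quantile((p - p0) / max(p1[j], 1e-300), aH, bH, data$pi0[j], 1)
    }
    ci_low[j] <- qfun(0.025); ci_high[j] <- qfun(0.975)
  }

  new_posterior_summary(labels = data$labels, prob_exceed = p1,
                        post_mean_pi = post_mean_pi, ci_low = ci_low,
                        ci_high = ci_high, method = method)
}

.indicator_gibbs <- function(logm, a0, b0, config) {
  J <- nrow(logm)
  n_burn <- floor(config$iterations * config$burn_in_fraction)
  n_keep <- config$iterations - n_burn
  acc <- numeric(J)
  for (ch in seq_len(config$chains)) {
    set.seed(.substream(config$seed, ch))
    g <- stats::rbinom(J, 1, 0.5)
    for (it in seq_len(config$iterations)) {
      for (j in seq_len(J)) {
        t_mj <- sum(g[-j])
        l1 <- logm[j, 2] + log(a0 + t_mj)
        l0 <- logm[j, 1] + log(b0 + J - 1 - t_mj)
        p1 <- 1 / (1 + exp(l0 - l1))
        g[j] <- as.integer(stats::runif(1) < p1)
      }
      if (it > n_burn) acc <- acc + g
    }
  }
  acc / (config$chains * n_keep)
}
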