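# Deterministic nested-quadrature engine for the normal-family borrowing
# models. The outer integral is a 2-D Riemann sum over (mu, log sigma); the
# inner per-basket integrals over gamma use mode-recentred Gauss-Legendre
# panels split at the decision cutoff, so tail probabilities P(gamma > cut)
# carry full quadrature accuracy rather than indicator-weighting error.

.gl_cache <- new.env(parent = emptyenv())

.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- list(x = g$x, w = g$w)
  }
  .gl_cache[[key]]
}

#' Quadrature grid configuration
#'
#' Controls the deterministic posterior engine: the outer grid over the
#' population mean \eqn{\mu} and log standard deviation \eqn{\log\sigma},
#' and the number of Gauss-Legendre nodes per inner integration panel.
#' Defaults cover \eqn{\mu \in [-15, 15]} and \eqn{\sigma \in [0.01, 50]}
#' (log-spaced), generous for effects on the logit scale.
#'
#' @param mu_range,mu_points outer grid for the population mean.
#' @param sigma_range,sigma_points outer grid for the population standard
#'   deviation (log-spaced).
#' @param panel_nodes Gauss-Legendre nodes per inner panel (4 panels are
#'   used, recentred at the conditional mode and split at the cutoff).
#' @param gamma_range,gamma_points fixed grid on the transformed scale used
#'   for posterior densities, means and credible intervals.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(mu_range = c(-15, 15), mu_points = 201,
                        sigma_range = c(0.01, 50), sigma_points = 201,
                        panel_nodes = 32,
                        gamma_range = c(-12, 12), gamma_points = 241) {
  stopifnot(mu_range[1] < mu_range[2], mu_points >= 11,
            sigma_range[1] > 0, sigma_range[1] < sigma_range[2],
            sigma_points >= 11, panel_nodes >= 8, gamma_points >= 51)
  structure(list(mu_range = mu_range, mu_points = as.integer(mu_points),
                 sigma_range = sigma_range, sigma_points = as.integer(sigma_points),
                 panel_nodes = as.integer(panel_nodes),
                 gamma_range = gamma_range, gamma_points = as.integer(gamma_points)),
            class = "grid_config")
}

# stable log(1 + exp(z))
.log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Conditional quadrature for one basket: integrate
#   Bin(y | n, pi(gamma)) * N(gamma; mu, sigma^2)
# over gamma, where pi(gamma) = plogis(gamma + off). Vectorized over cells
# (mu, sigma). Returns the log normalizing constant and the fraction of
# posterior mass above `cut`.
.cond_quad <- function(y, n, off, cut, mu, sigma, nq = 32) {
  C <- length(mu)
  stopifnot(length(sigma) == C)
  isig2 <- 1 / sigma^2
  lc <- lchoose(n, y)

  f_eval <- function(g) {
    z <- g + off
    lc + y * z - n * .log1pexp(z) - 0.5 * (g - mu)^2 * isig2 -
      log(sigma) - 0.5 * log(2 * pi)
  }

  # damped Newton for the (strictly concave) conditional log density
  m <- rep_len(mu, C)
  for (it in 1:60) {
    p <- stats::plogis(m + off)
    g1 <- y - n * p - (m - mu) * isig2
    g2 <- -n * p * (1 - p) - isig2
    step <- pmax(pmin(-g1 / g2, 4), -4)
    m <- m + step
    if (max(abs(step)) < 1e-10) break
  }
  p <- stats::plogis(m + off)
  s <- 1 / sqrt(n * p * (1 - p) + isig2)

  lo <- pmin(m - 8 * s, mu - 7 * sigma)
  hi <- pmax(m + 8 * s, mu + 7 * sigma)
  clamp <- function(x) pmin(pmax(x, lo), hi)
  v1 <- clamp(m - 8 * s); v2 <- clamp(rep_len(cut, C)); v3 <- clamp(m + 8 * s)
  # rowwise sort of the three interior breakpoints
  b1 <- pmin(v1, v2, v3)
  b3 <- pmax(v1, v2, v3)
  b2 <- (v1 + v2 + v3) - b1 - b3
  breaks <- cbind(lo, b1, b2, b3, hi)

  gl <- .gl_nodes(nq)
  fm <- f_eval(m)
  Z <- numeric(C); above <- numeric(C)
  for (pn in 1:4) {
    a <- breaks[, pn]; b <- breaks[, pn + 1]
    half <- (b - a) / 2
    ctr <- (a + b) / 2
    gz <- outer(half, gl$x) + ctr          # C x nq node matrix
    vals <- exp(f_eval(as.vector(gz)) - rep(fm, times = nq))
    dim(vals) <- c(C, nq)
    pz <- half * as.vector(vals %*% gl$w)
    Z <- Z + pz
    above <- above + pz * (a >= cut - 1e-12)
  }
  list(logZ = fm + log(Z), frac_above = pmin(pmax(above / Z, 0), 1),
       mode = m, scale = s)
}

# outer-grid cells for a prior: mu, sigma vectors plus log prior weights
# (including the sigma Jacobian and grid spacing). independent_normal
# collapses to a single degenerate cell.
.prior_cells <- function(prior, grid) {
  if (prior$family == "independent_normal") {
    return(list(mu = prior$mean, sigma = prior$sd, lw = 0))
  }
  if (prior$family != "hier_normal")
    stop("the quadrature engine supports independent_normal and hier_normal priors")
  if (prior$sigma_prior$kind == "fixed") {
    mu <- seq(grid$mu_range[1], grid$mu_range[2], length.out = grid$mu_points)
    dmu <- mu[2] - mu[1]
    lw <- stats::dnorm(mu, prior$mu_mean, prior$mu_sd, log = TRUE) + log(dmu)
    return(list(mu = mu, sigma = rep(prior$sigma_prior$sigma, length(mu)), lw = lw))
  }
  mu <- seq(grid$mu_range[1], grid$mu_range[2], length.out = grid$mu_points)
  ls <- seq(log(grid$sigma_range[1]), log(grid$sigma_range[2]),
            length.out = grid$sigma_points)
  dmu <- mu[2] - mu[1]; dls <- ls[2] - ls[1]
  sig <- exp(ls)
  lw_mu <- stats::dnorm(mu, prior$mu_mean, prior$mu_sd, log = TRUE) + log(dmu)
  lw_sig <- .log_sigma_density(prior$sigma_prior, sig) + ls + log(dls)
  cells_mu <- rep(mu, times = length(sig))
  cells_sig <- rep(sig, each = length(mu))
  list(mu = cells_mu, sigma = cells_sig,
       lw = rep(lw_mu, times = length(sig)) + rep(lw_sig, each = length(mu)))
}

# gamma offset per basket for the real-valued transforms
.gamma_offset <- function(transform, pi0) {
  switch(transform$kind,
    logit = rep(0, length(pi0)),
    logit_increment = stats::qlogis(pi0),
    stop("the quadrature engine requires the logit or logit_increment transform"))
}

#' Deterministic posterior computation by nested quadrature
#'
#' Computes the posterior exactly (to quadrature accuracy) for the
#' no-borrowing independent-normal model and the hierarchical-normal model:
#' an outer 2-D grid over \eqn{(\mu, \log\sigma)} weighted by the marginal
#' likelihood, with per-basket inner Gauss-Legendre integrals over the
#' transformed effect recentred at the conditional mode and split at the
#' decision cutoff. Deterministic for a fixed grid, so it serves both as a
#' fast inference engine and as an independent cross-check of the MCMC
#' sampler.
#'
#' @param model a [model_spec] with a `logit` or `logit_increment`
#'   transformation and an `independent_normal` or `hier_normal` prior.
#' @param data a [basket_data] object.
#' @param grid a [grid_config].
#' @return A `posterior_summary` (see [fit_basket()]) with exceedance
#'   probabilities, rate means and 95\% equal-tailed credible intervals per
#'   basket, plus posterior summaries of \eqn{(\mu, \sigma)} in `$hyper`
#'   and the log marginal likelihood in `$log_marginal`.
#' @examples
#' fit_oracle(named_prior("prior_II"),
#'            basket_data(NULL, y = c(2, 6), n = c(20, 20), pi0 = 0.2))
#' @export
fit_oracle <- function(model, data, grid = grid_config()) {
  stopifnot(inherits(model, "model_spec"), inherits(data, "basket_data"),
            inherits(grid, "grid_config"))
  J <- length(data$y)
  off <- .gamma_offset(model$transform, data$pi0)
  cut <- .gamma_cut(model$transform, data$pi0)
  cells <- .prior_cells(model$prior, grid)
  C <- length(cells$mu)

  logZ <- matrix(0, C, J)
  frac <- matrix(0, C, J)
  for (j in seq_len(J)) {
    q <- .cond_quad(data$y[j], data$n[j], off[j], cut[j],
                    rep_len(cells$mu, C), rep_len(cells$sigma, C),
                    nq = grid$panel_nodes)
    logZ[, j] <- q$logZ
    frac[, j] <- q$frac_above
  }
  lp <- cells$lw + rowSums(logZ)
  mx <- max(lp)
  w <- exp(lp - mx)
  logml <- mx + log(sum(w))
  w <- w / sum(w)
  prob_exceed <- as.vector(crossprod(frac, w))

  # per-basket marginal densities of gamma on a fixed grid (cells with
  # negligible posterior weight are dropped first)
  keep <- which(w > 1e-14)
  keep <- keep[order(w[keep], decreasing = TRUE)]
  keep <- keep[cumsum(w[keep]) < 1 - 1e-12 + w[keep][1]]
  wk <- w[keep] / sum(w[keep])
  gg <- seq(grid$gamma_range[1], grid$gamma_range[2],
            length.out = grid$gamma_points)
  post_mean_pi <- ci_low <- ci_high <- numeric(J)
  for (j in seq_len(J)) {
    dens <- .marginal_gamma_density(data$y[j], data$n[j], off[j],
                                    cells$mu[keep], cells$sigma[keep],
                                    logZ[keep, j], wk, gg)
    sm <- .density_summaries(gg, dens, off[j])
    post_mean_pi[j] <- sm$mean
    ci_low[j] <- sm$q[1]; ci_high[j] <- sm$q[2]
  }

  hyper <- if (model$prior$family == "hier_normal") {
    list(mu_mean = sum(w * cells$mu),
         mu_sd = sqrt(max(sum(w * cells$mu^2) - sum(w * cells$mu)^2, 0)),
         sigma_mean = sum(w * cells$sigma),
         sigma_sd = sqrt(max(sum(w * cells$sigma^2) - sum(w * cells$sigma)^2, 0)))
  } else NULL

  new_posterior_summary(labels = data$labels, prob_exceed = prob_exceed,
                        post_mean_pi = post_mean_pi, ci_low = ci_low,
                        ci_high = ci_high, method = "oracle",
                        hyper = hyper, log_marginal = logml)
}

# weighted conditional densities of gamma for one basket on grid gg
.marginal_gamma_density <- function(y, n, off, mu, sigma, logZ, w, gg) {
  C <- length(mu)
  lc <- lchoose(n, y)
  dens <- numeric(length(gg))
  for (i in seq(1, length(gg), by = 48)) {
    idx <- i:min(i + 47, length(gg))
    g <- gg[idx]
    G <- outer(rep(1, C), g)
    z <- G + off
    lf <- lc + y * z - n * .log1pexp(z) -
      0.5 * ((G - mu)^2) / sigma^2 -
      log(sigma) - 0.5 * log(2 * pi) - logZ
    dens[idx] <- as.vector(crossprod(exp(lf), w))
  }
  dens
}

# mean of pi and equal-tailed 95% interval from a gamma-scale density;
# mass beyond the grid edges is treated as atoms at the edges (which map to
# rates within ~1e-4 of 0 or 1)
.density_summaries <- function(gg, dens, off, probs = c(0.025, 0.975)) {
  h <- diff(gg)
  seg <- h * (dens[-length(dens)] + dens[-1]) / 2
  total <- sum(seg)
  edge <- max(1 - total, 0)
  e_ends <- dens[c(1, length(dens))] + 1e-300
  edge_lo <- edge * e_ends[1] / sum(e_ends)
  edge_hi <- edge - edge_lo
  pi_g <- stats::plogis(gg + off)
  mean_pi <- sum(seg * (pi_g[-length(pi_g)] + pi_g[-1]) / 2) +
    edge_lo * pi_g[1] + edge_hi * pi_g[length(pi_g)]
  cdf <- edge_lo + c(0, cumsum(seg))
  q <- vapply(probs, function(p) {
    if (p <= cdf[1]) return(pi_g[1])
    if (p >= cdf[length(cdf)]) return(pi_g[length(pi_g)])
    k <- findInterval(p, cdf)
    frac <- (p - cdf[k]) / max(cdf[k + 1] - cdf[k], 1e-300)
    stats::plogis(gg[k] + frac * (gg[k + 1] - gg[k]) + off)
  }, numeric(1))
  list(mean = mean_pi, q = q)
}
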