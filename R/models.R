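#' Hyperpriors for the hierarchical standard deviation
#'
#' The population standard deviation \eqn{\sigma} of the basket effects
#' controls the degree of borrowing: small \eqn{\sigma} forces the
#' transformed rates together (strong shrinkage), large \eqn{\sigma} leaves
#' them essentially independent. Available hyperpriors:
#' `half_normal(A)` and `half_t(nu, A)` are weakly informative priors on
#' \eqn{\sigma} itself (the half-Cauchy is `half_t(1, A)`, the half-normal
#' is the \eqn{\nu \to \infty} limit); `inv_gamma(alpha, beta)` is the
#' conjugate inverse-gamma prior on the variance \eqn{\sigma^2};
#' `fixed_sigma(sigma)` pins the value.
#'
#' @param A scale parameter, > 0.
#' @param nu degrees of freedom, >= 1.
#' @param alpha,beta inverse-gamma shape and rate, > 0.
#' @param sigma fixed value, > 0.
#' @return An object of class `sigma_hyperprior`.
#' @name sigma_hyperprior
NULL

#' @rdname sigma_hyperprior
#' @export
half_normal <- function(A) {
  stopifnot(is.numeric(A), A > 0)
  structure(list(kind = "half_normal", A = A), class = "sigma_hyperprior")
}

#' @rdname sigma_hyperprior
#' @export
half_t <- function(nu, A) {
  stopifnot(is.numeric(nu), nu >= 1, is.numeric(A), A > 0)
  structure(list(kind = "half_t", nu = nu, A = A), class = "sigma_hyperprior")
}

#' @rdname sigma_hyperprior
#' @export
inv_gamma <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(kind = "inv_gamma", alpha = alpha, beta = beta),
            class = "sigma_hyperprior")
}

#' @rdname sigma_hyperprior
#' @export
fixed_sigma <- function(sigma) {
  stopifnot(sigma > 0)
  structure(list(kind = "fixed", sigma = sigma), class = "sigma_hyperprior")
}

# log density of sigma under a sigma_hyperprior, on the sigma scale
# (the inverse-gamma kind is a density on sigma^2; the 2*sigma Jacobian is
# included so all kinds are comparable as densities in sigma)
.log_sigma_density <- function(sp, sigma) {
  out <- rep(-Inf, length(sigma))
  ok <- is.finite(sigma) & sigma >= 0
  s <- sigma[ok]
  out[ok] <- switch(sp$kind,
    half_normal = log(2) + stats::dnorm(s, 0, sp$A, log = TRUE),
    half_t = log(2) - log(sp$A) + stats::dt(s / sp$A, df = sp$nu, log = TRUE),
    inv_gamma = ifelse(s > 0,
      sp$alpha * log(sp$beta) - lgamma(sp$alpha) -
        (sp$alpha + 1) * log(s^2) - sp$beta / s^2 + log(2 * pmax(s, .Machine$double.xmin)),
      -Inf),
    fixed = ifelse(abs(s - sp$sigma) < 1e-12, 0, -Inf))
  out
}

.normal_params <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  list(mean = mean, sd = sd)
}

#' Prior families for the transformed basket effects
#'
#' Each constructor returns a `prior_spec` describing the population model
#' \eqn{G(\theta)} for the transformed rates \eqn{\gamma_j}, which determines
#' *how* information is borrowed:
#' \describe{
#'   \item{`independent_normal(mean, sd)`}{\eqn{\gamma_j \sim} iid
#'     N(mean, sd^2) with fixed parameters - no borrowing (a wide sd gives an
#'     essentially flat, independent analysis per basket).}
#'   \item{`hier_normal(mu_mean, mu_sd, sigma_prior)`}{\eqn{\gamma_j \mid
#'     \mu, \sigma \sim} iid N(\eqn{\mu, \sigma^2}) with
#'     \eqn{\mu \sim} N(mu_mean, mu_sd^2) and a [sigma_hyperprior] on
#'     \eqn{\sigma}; the canonical hierarchical (shrinkage) model.}
#'   \item{`mixture_normal(K, weight_conc, mu_mean, mu_sd, sigma_prior)`}{a
#'     finite mixture \eqn{\gamma_j \sim \sum_k w_k N(\mu_k, \sigma_k^2)}
#'     with a symmetric Dirichlet(weight_conc) prior on the weights;
#'     equivalently each basket carries a latent subgroup label and borrowing
#'     happens within subgroups only.}
#'   \item{`partition_bma(within_mean, within_sd, lambda)`}{Bayesian model
#'     averaging over all set partitions of the baskets: within a subset all
#'     baskets share a single \eqn{\gamma} with a N(within_mean,
#'     within_sd^2) prior; the partition prior is uniform, optionally tilted
#'     by \eqn{\exp(-\lambda \times \#subsets)}.}
#'   \item{`indicator_borrow(prob_prior, beta_low, beta_high)`}{borrowing at
#'     the hypothesis level: \eqn{\gamma_j = 1(\pi_j > \pi_{0j}) \sim}
#'     Bernoulli(\eqn{\rho}) with \eqn{\rho \sim} Beta(prob_prior), and
#'     conditional truncated-beta priors for \eqn{\pi_j} on
#'     \eqn{[0, \pi_{0j}]} (shapes `beta_low`) or \eqn{(\pi_{0j}, 1]}
#'     (shapes `beta_high`).}
#' }
#'
#' @param mean,sd fixed normal parameters (independent model).
#' @param mu_mean,mu_sd normal prior parameters for the population mean.
#' @param sigma_prior a [sigma_hyperprior].
#' @param K number of mixture components, >= 1.
#' @param weight_conc symmetric Dirichlet concentration, > 0.
#' @param within_mean,within_sd normal prior for the shared effect within a
#'   partition subset.
#' @param lambda partition-size tilt; 0 gives the uniform partition prior.
#' @param prob_prior length-2 beta shapes for the Bernoulli success rate.
#' @param beta_low,beta_high length-2 beta shapes for the conditional rate
#'   priors below and above the reference rate.
#' @return An object of class `prior_spec`.
#' @name prior_spec
NULL

#' @rdname prior_spec
#' @export
independent_normal <- function(mean = 0, sd = 100) {
  p <- .normal_params(mean, sd)
  structure(list(family = "independent_normal", mean = p$mean, sd = p$sd),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
hier_normal <- function(mu_mean = 0, mu_sd = 100, sigma_prior = half_normal(3)) {
  stopifnot(inherits(sigma_prior, "sigma_hyperprior"))
  p <- .normal_params(mu_mean, mu_sd)
  structure(list(family = "hier_normal", mu_mean = p$mean, mu_sd = p$sd,
                 sigma_prior = sigma_prior),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
mixture_normal <- function(K, weight_conc = 1, mu_mean = 0, mu_sd = 10,
                           sigma_prior = half_normal(3)) {
  stopifnot(K >= 1, weight_conc > 0, inherits(sigma_prior, "sigma_hyperprior"))
  p <- .normal_params(mu_mean, mu_sd)
  structure(list(family = "mixture_normal", K = as.integer(K),
                 weight_conc = weight_conc, mu_mean = p$mean, mu_sd = p$sd,
                 sigma_prior = sigma_prior),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
partition_bma <- function(within_mean = 0, within_sd = 2, lambda = 0) {
  p <- .normal_params(within_mean, within_sd)
  stopifnot(is.finite(lambda))
  structure(list(family = "partition_bma", within_mean = p$mean,
                 within_sd = p$sd, lambda = lambda),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
indicator_borrow <- function(prob_prior = c(1, 1), beta_low = c(1, 1),
                             beta_high = c(1, 1)) {
  chk <- function(x, what) {
    if (length(x) != 2L || any(x <= 0)) stop(what, " must be two positive beta shapes")
    as.numeric(x)
  }
  structure(list(family = "indicator_borrow",
                 prob_prior = chk(prob_prior, "prob_prior"),
                 beta_low = chk(beta_low, "beta_low"),
                 beta_high = chk(beta_high, "beta_high")),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior family:", x$family, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Model specification: transformation + prior
#'
#' Pairs a [transform_spec] (what is borrowed) with a [prior_spec] (how it is
#' borrowed). The hypothesis-indicator transformation requires the
#' `indicator_borrow` prior and vice versa; all other priors require a
#' real-valued transformation.
#'
#' @param transform a [transform_spec].
#' @param prior a [prior_spec].
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(transform_spec("logit_increment"), hier_normal())
#' @export
model_spec <- function(transform, prior) {
  stopifnot(inherits(transform, "transform_spec"), inherits(prior, "prior_spec"))
  ind_t <- transform$kind == "hypothesis_indicator"
  ind_p <- prior$family == "indicator_borrow"
  if (ind_t != ind_p)
    stop("the hypothesis_indicator transform and the indicator_borrow prior ",
         "must be used together")
  structure(list(transform = transform, prior = prior), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  print(x$transform); print(x$prior)
  invisible(x)
}

#' The three benchmark borrowing priors
#'
#' Named borrowing models for the logit-increment scale
#' \eqn{\gamma_j = \mathrm{logit}(\pi_j) - \mathrm{logit}(\pi_{0j})}:
#' \describe{
#'   \item{`prior_I`}{no borrowing: \eqn{\gamma_j \sim} iid N(0, 100^2).}
#'   \item{`prior_II`}{moderate borrowing: \eqn{\gamma_j \sim N(\mu,
#'     \sigma^2)}, \eqn{\mu \sim N(0, 100^2)}, \eqn{\sigma \sim}
#'     Half-N(3).}
#'   \item{`prior_III`}{strong borrowing: as `prior_II` but \eqn{\sigma \sim}
#'     Half-N(0.3).}
#' }
#'
#' @param name one of `"prior_I"`, `"prior_II"`, `"prior_III"`.
#' @return A [model_spec].
#' @examples
#' named_prior("prior_II")
#' @export
named_prior <- function(name) {
  valid <- c("prior_I", "prior_II", "prior_III")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown named prior; valid names are: ", paste(valid, collapse = ", "))
  tr <- transform_spec("logit_increment")
  pr <- switch(name,
    prior_I = independent_normal(0, 100),
    prior_II = hier_normal(0, 100, half_normal(3)),
    prior_III = hier_normal(0, 100, half_normal(0.3)))
  model_spec(tr, pr)
}

#' Joint log density of the transformed effects given hyperparameters
#'
#' Evaluates \eqn{\log \prod_j p(\gamma_j \mid \theta)} for the normal-family
#' priors (and the Bernoulli pmf for the indicator prior). The mixture
#' evaluates, per basket, the log of the weighted sum of component normal
#' densities.
#'
#' @param prior a [prior_spec].
#' @param gamma numeric vector of transformed effects.
#' @param theta named list of hyperparameter values: `mu`, `sigma` for
#'   `hier_normal`; `mu`, `sigma`, `w` (each length K) for `mixture_normal`;
#'   `rho` for `indicator_borrow`; ignored for `independent_normal`.
#' @return A single log density value.
#' @export
log_density_gamma <- function(prior, gamma, theta = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  switch(prior$family,
    independent_normal = sum(stats::dnorm(gamma, prior$mean, prior$sd, log = TRUE)),
    hier_normal = {
      if (!is.finite(theta$mu) || !is.finite(theta$sigma)) stop("theta must be finite")
      if (theta$sigma <= 0) return(-Inf)
      sum(stats::dnorm(gamma, theta$mu, theta$sigma, log = TRUE))
    },
    mixture_normal = {
      K <- prior$K
      if (length(theta$mu) != K || length(theta$sigma) != K || length(theta$w) != K)
        stop("theta dimensions must match K")
      if (any(theta$sigma <= 0) || any(theta$w < 0)) return(-Inf)
      lw <- log(theta$w / sum(theta$w))
      comp <- vapply(seq_len(K), function(k)
        stats::dnorm(gamma, theta$mu[k], theta$sigma[k], log = TRUE) + lw[k],
        numeric(length(gamma)))
      comp <- matrix(comp, nrow = length(gamma))
      m <- apply(comp, 1, max)
      sum(m + log(rowSums(exp(comp - m))))
    },
    indicator_borrow = {
      if (!all(gamma %in% c(0, 1))) stop("indicator gamma must be 0/1")
      rho <- theta$rho
      if (rho < 0 || rho > 1) return(-Inf)
      sum(gamma * log(rho) + (1 - gamma) * log1p(-rho))
    },
    stop("log_density_gamma is not defined for family ", prior$family))
}

#' Log hyperprior density
#'
#' Sum of the log densities of the population-mean prior, the
#' [sigma_hyperprior] on the population standard deviation, and - for the
#' mixture - the symmetric Dirichlet prior on the weights. States outside
#' the support (e.g. \eqn{\sigma < 0}) return `-Inf` rather than raising an
#' error, so samplers can treat them as rejected proposals.
#'
#' @inheritParams log_density_gamma
#' @return A single log density value (possibly `-Inf`).
#' @export
log_hyperprior <- function(prior, theta) {
  stopifnot(inherits(prior, "prior_spec"))
  switch(prior$family,
    independent_normal = 0,
    hier_normal = {
      if (!is.finite(theta$mu)) return(-Inf)
      stats::dnorm(theta$mu, prior$mu_mean, prior$mu_sd, log = TRUE) +
        .log_sigma_density(prior$sigma_prior, theta$sigma)
    },
    mixture_normal = {
      if (any(!is.finite(theta$mu))) return(-Inf)
      w <- theta$w
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8) return(-Inf)
      a <- prior$weight_conc
      ld_w <- lgamma(prior$K * a) - prior$K * lgamma(a) + sum((a - 1) * log(w))
      sum(stats::dnorm(theta$mu, prior$mu_mean, prior$mu_sd, log = TRUE)) +
        sum(.log_sigma_density(prior$sigma_prior, theta$sigma)) + ld_w
    },
    indicator_borrow = {
      rho <- theta$rho
      if (!is.finite(rho) || rho < 0 || rho > 1) return(-Inf)
      stats::dbeta(rho, prior$prob_prior[1], prior$prob_prior[2], log = TRUE)
    },
    partition_bma = 0,
    stop("log_hyperprior is not defined for family ", prior$family))
}

#' Serialize or restore a model specification
#'
#' `model_to_list()` flattens a [model_spec] into plain lists suitable for
#' YAML/JSON configuration blocks; `model_from_list()` restores it.
#'
#' @param model a [model_spec].
#' @param x a list produced by `model_to_list()` (or parsed from YAML/JSON).
#' @return A plain list, or a restored [model_spec].
#' @export
model_to_list <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  pr <- unclass(model$prior)
  if (!is.null(pr$sigma_prior)) pr$sigma_prior <- unclass(pr$sigma_prior)
  list(transform = model$transform$kind, prior = pr)
}

#' @rdname model_to_list
#' @export
model_from_list <- function(x) {
  if (identical(names(x), NULL) || is.null(x$prior) || is.null(x$transform))
    stop("expected a list with 'transform' and 'prior' entries")
  pr <- x$prior
  sp <- NULL
  if (!is.null(pr$sigma_prior)) {
    s <- pr$sigma_prior
    sp <- switch(s$kind,
      half_normal = half_normal(s$A),
      half_t = half_t(s$nu, s$A),
      inv_gamma = inv_gamma(s$alpha, s$beta),
      fixed = fixed_sigma(s$sigma),
      stop("unknown sigma hyperprior kind: ", s$kind))
  }
  prior <- switch(pr$family,
    independent_normal = independent_normal(pr$mean, pr$sd),
    hier_normal = hier_normal(pr$mu_mean, pr$mu_sd, sp),
    mixture_normal = mixture_normal(pr$K, pr$weight_conc, pr$mu_mean, pr$mu_sd, sp),
    partition_bma = partition_bma(pr$within_mean, pr$within_sd, pr$lambda),
    indicator_borrow = indicator_borrow(unlist(pr$prob_prior),
                                        unlist(pr$beta_low), unlist(pr$beta_high)),
    stop("unknown prior family: ", pr$family))
  model_spec(transform_spec(x$transform), prior)
}
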