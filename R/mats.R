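# Multi-arm two-stage (MATS) double-basket model for phase I dose
# optimization: a higher dose is expanded in several indications (stage 1);
# indications where it shows promising efficacy are selected for a
# randomized comparison of both doses (stage 2). Information is borrowed
# across indications through hierarchical priors on the efficacy increment
# of the high dose over the reference rate (gamma1, on the logit scale) and
# on the high-vs-low dose contrast (gamma2, log-normal by default, which
# encodes the assumption that response increases with dose).

#' MATS trial data
#'
#' Arm-level data for a two-dose, J-indication, two-stage design. Arms are
#' identified by (dose, indication, stage) with dose 1 = higher, dose 2 =
#' lower. Stage 1 enrolls only the higher dose; stage 2 enrolls both doses,
#' and only in indications selected at the interim.
#'
#' @param arms a data frame with columns `dose` (1 or 2), `indication`
#'   (1..J), `stage` (1 or 2), `y`, `n`.
#' @param pi0 reference rate per indication (scalar recycled).
#' @param selected optional logical vector per indication; defaults to
#'   "has stage-2 data".
#' @param labels optional indication names.
#' @return An object of class `mats_data` holding the count arrays `y[i,j,k]`
#'   and `n[i,j,k]` (NA for arms not enrolled), selection flags `D`, and `pi0`.
#' @export
mats_data <- function(arms, pi0, selected = NULL, labels = NULL) {
  need <- c("dose", "indication", "stage", "y", "n")
  if (!all(need %in% names(arms)))
    stop("arms must have columns ", paste(need, collapse = ", "))
  J <- max(arms$indication)
  if (length(pi0) == 1L) pi0 <- rep(pi0, J)
  stopifnot(length(pi0) == J, all(pi0 > 0), all(pi0 < 1))
  if (is.null(labels)) labels <- paste0("indication_", seq_len(J))
  y <- array(NA_integer_, c(2, J, 2)); n <- array(NA_integer_, c(2, J, 2))
  for (r in seq_len(nrow(arms))) {
    i <- arms$dose[r]; j <- arms$indication[r]; k <- arms$stage[r]
    if (!(i %in% 1:2) || !(k %in% 1:2) || j < 1 || j > J)
      stop(sprintf("arm row %d: invalid (dose, indication, stage)", r))
    if (k == 1 && i != 1)
      stop(sprintf("arm row %d: stage 1 enrolls only the higher dose", r))
    if (is.na(arms$y[r]) || is.na(arms$n[r]) || arms$n[r] < 0 ||
        arms$y[r] < 0 || arms$y[r] > arms$n[r])
      stop(sprintf("arm row %d: need 0 <= y <= n", r))
    y[i, j, k] <- as.integer(arms$y[r]); n[i, j, k] <- as.integer(arms$n[r])
  }
  has_stage2 <- vapply(seq_len(J), function(j) any(!is.na(n[, j, 2])), logical(1))
  if (is.null(selected)) selected <- has_stage2
  selected <- as.logical(rep_len(selected, J))
  if (any(has_stage2 & !selected))
    stop("stage-2 data present for an indication not flagged as selected")
  structure(list(y = y, n = n, D = selected, pi0 = as.numeric(pi0),
                 labels = labels, J = J),
            class = "mats_data")
}

#' @export
as.data.frame.mats_data <- function(x, ...) {
  rows <- list()
  for (i in 1:2) for (j in seq_len(x$J)) for (k in 1:2) {
    if (!is.na(x$n[i, j, k]))
      rows[[length(rows) + 1]] <- data.frame(
        dose = i, indication = j, stage = k,
        y = x$y[i, j, k], n = x$n[i, j, k],
        selected = as.integer(x$D[j]))
  }
  do.call(rbind, rows)
}

#' @export
print.mats_data <- function(x, ...) {
  cat(sprintf("MATS data: %d indications; selected for stage 2: %s\n",
              x$J, paste(which(x$D), collapse = ", ")))
  print(as.data.frame(x))
  invisible(x)
}

#' Read or write MATS data as long-format CSV
#'
#' Columns `dose,indication,stage,y,n,selected`.
#'
#' @param data a [mats_data] object.
#' @param path file path.
#' @param pi0 reference rate(s) used when reading.
#' @return `write_mats()` returns `path` invisibly; `load_mats()` a
#'   [mats_data].
#' @export
write_mats <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mats
#' @export
load_mats <- function(path, pi0) {
  d <- utils::read.csv(path, comment.char = "#")
  sel <- NULL
  if ("selected" %in% names(d)) {
    J <- max(d$indication)
    sel <- vapply(seq_len(J), function(j)
      any(d$selected[d$indication == j] == 1), logical(1))
  }
  mats_data(d, pi0, selected = sel)
}

#' MATS hierarchical prior
#'
#' Population models for the two transformed quantities:
#' \eqn{\gamma_{1j} \sim N(\mu_1, \sigma_1^2)} (efficacy increment of the
#' high dose) and \eqn{\gamma_{2j} \sim \mathrm{LogNormal}(\mu_2,
#' \sigma_2^2)} (high-vs-low dose contrast, positive by construction),
#' with conjugate hyperpriors \eqn{\mu \sim N(m, s^2)} and
#' \eqn{\sigma^2 \sim \mathrm{InvGamma}(a, b)}. Setting
#' `neutral_gamma2 = TRUE` replaces the log-normal with a normal
#' population model, allowing the lower dose to be more efficacious.
#'
#' @param m1,s1,a1,b1 hyperparameters for the \eqn{\gamma_1} population.
#' @param m2,s2,a2,b2 hyperparameters for the \eqn{\gamma_2} population.
#' @param neutral_gamma2 use a normal (sign-neutral) population for
#'   \eqn{\gamma_2}.
#' @return An object of class `mats_prior`.
#' @export
mats_prior <- function(m1 = 0, s1 = 10, a1 = 0.1, b1 = 0.1,
                       m2 = 0, s2 = 10, a2 = 0.1, b2 = 0.1,
                       neutral_gamma2 = FALSE) {
  stopifnot(s1 > 0, a1 > 0, b1 > 0, s2 > 0, a2 > 0, b2 > 0)
  structure(list(m1 = m1, s1 = s1, a1 = a1, b1 = b1,
                 m2 = m2, s2 = s2, a2 = a2, b2 = b2,
                 neutral_gamma2 = isTRUE(neutral_gamma2)),
            class = "mats_prior")
}

#' MATS transformations
#'
#' \eqn{\gamma_{1j} = \mathrm{logit}(\pi_{1j}) - \mathrm{logit}(\pi_{0j})}
#' (high-dose increment over the reference rate) and
#' \eqn{\gamma_{2j} = \mathrm{logit}(\pi_{1j}) - \mathrm{logit}(\pi_{2j})}
#' (high-vs-low dose contrast).
#'
#' @param pi1,pi2 high- and low-dose response rates, strictly in (0,1).
#' @param pi0 reference rate, strictly in (0,1).
#' @return A list with elements `gamma1` and `gamma2`.
#' @examples
#' mats_transform(0.35, 0.20, 0.20)
#' @export
mats_transform <- function(pi1, pi2, pi0) {
  .check_unit_interior(pi1, "pi1"); .check_unit_interior(pi2, "pi2")
  .check_unit_interior(pi0, "pi0")
  list(gamma1 = stats::qlogis(pi1) - stats::qlogis(pi0),
       gamma2 = stats::qlogis(pi1) - stats::qlogis(pi2))
}

#' Fit the MATS hierarchical model
#'
#' Joint posterior over \eqn{(\gamma_1, \gamma_2, \mu_1, \sigma_1, \mu_2,
#' \sigma_2)} by MCMC: Metropolis updates on the per-indication
#' \eqn{\gamma_{1j}} and (log) \eqn{\gamma_{2j}}, conjugate Gibbs draws for
#' the population means and variances, and interweaved translation/rescale
#' updates on the population blocks. Stage-1 and stage-2 high-dose data
#' both inform \eqn{\pi_{1j}}; low-dose data enter only through stage 2 of
#' selected indications, via
#' \eqn{\mathrm{logit}(\pi_{2j}) = \mathrm{logit}(\pi_{1j}) - \gamma_{2j}}.
#' With the default log-normal contrast population, every posterior draw
#' satisfies \eqn{\pi_{1j} > \pi_{2j}}.
#'
#' @param data a [mats_data].
#' @param prior a [mats_prior].
#' @param config an [mcmc_config].
#' @return An object of class `mats_summary`: a data frame with, per
#'   indication, posterior means and 95\% credible intervals of
#'   \eqn{\pi_{1j}} and \eqn{\pi_{2j}}, and the posterior probabilities
#'   \eqn{\Pr(\pi_{1j} > \pi_{0j})}, \eqn{\Pr(\pi_{2j} > \pi_{0j})} and
#'   \eqn{\Pr(\pi_{1j} > \pi_{2j})}; diagnostics in `attr(, "diagnostics")`.
#' @export
fit_mats <- function(data, prior, config) {
  stopifnot(inherits(data, "mats_data"), inherits(prior, "mats_prior"),
            inherits(config, "mcmc_config"))
  J <- data$J
  if (all(is.na(data$n[1, , 1])))
    stop("at least one indication needs stage-1 data")
  for (j in which(data$D)) {
    if (all(is.na(data$n[, j, 2])))
      stop(sprintf("indication %d is selected but has no stage-2 data", j))
  }
  off <- stats::qlogis(data$pi0)
  y1 <- function(j) c(data$y[1, j, 1], data$y[1, j, 2])
  n1 <- function(j) c(data$n[1, j, 1], data$n[1, j, 2])
  # per-indication log likelihood given (g1, gamma2)
  loglik_j <- function(j, g1j, gam2j) {
    z1 <- g1j + off[j]
    ll <- 0
    ys <- y1(j); ns <- n1(j)
    for (t in 1:2) if (!is.na(ns[t]))
      ll <- ll + ys[t] * z1 - ns[t] * .log1pexp(z1)
    if (!is.na(data$n[2, j, 2])) {
      z2 <- z1 - gam2j
      ll <- ll + data$y[2, j, 2] * z2 - data$n[2, j, 2] * .log1pexp(z2)
    }
    ll
  }
  has_low <- !is.na(data$n[2, , 2])
  lognorm <- !prior$neutral_gamma2

  n_burn <- floor(config$iterations * config$burn_in_fraction)
  n_keep <- config$iterations - n_burn
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(.substream(config$seed, ch))
    g1 <- rep(0, J)
    h2 <- rep(if (lognorm) log(0.5) else 0, J)  # h2 = log(gamma2) or gamma2
    mu1 <- 0; v1 <- 1; mu2 <- prior$m2; v2 <- 1
    ls1 <- rep(log(0.8), J); ls2 <- rep(log(0.8), J)
    a1c <- n1c <- rep(0, J); a2c <- n2c <- rep(0, J)
    gam2 <- if (lognorm) exp(h2) else h2
    ll <- vapply(seq_len(J), function(j) loglik_j(j, g1[j], gam2[j]), numeric(1))
    d_g1 <- matrix(0, n_keep, J); d_h2 <- matrix(0, n_keep, J)
    d_hyp <- matrix(0, n_keep, 4)
    for (it in seq_len(config$iterations)) {
      # gamma1: Metropolis per indication
      for (j in seq_len(J)) {
        gp <- g1[j] + stats::rnorm(1) * exp(ls1[j])
        llp <- loglik_j(j, gp, gam2[j])
        d <- llp - ll[j] +
          stats::dnorm(gp, mu1, sqrt(v1), log = TRUE) -
          stats::dnorm(g1[j], mu1, sqrt(v1), log = TRUE)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          g1[j] <- gp; ll[j] <- llp; a1c[j] <- a1c[j] + 1
        }
        n1c[j] <- n1c[j] + 1
      }
      # h2 (contrast scale): Metropolis where the low dose has data,
      # exact prior draw elsewhere
      for (j in seq_len(J)) {
        if (!has_low[j]) {
          h2[j] <- stats::rnorm(1, mu2, sqrt(v2))
          gam2[j] <- if (lognorm) exp(h2[j]) else h2[j]
          next
        }
        hp <- h2[j] + stats::rnorm(1) * exp(ls2[j])
        gp2 <- if (lognorm) exp(hp) else hp
        llp <- loglik_j(j, g1[j], gp2)
        d <- llp - ll[j] +
          stats::dnorm(hp, mu2, sqrt(v2), log = TRUE) -
          stats::dnorm(h2[j], mu2, sqrt(v2), log = TRUE)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          h2[j] <- hp; gam2[j] <- gp2; ll[j] <- llp; a2c[j] <- a2c[j] + 1
        }
        n2c[j] <- n2c[j] + 1
      }
      # conjugate hyper draws
      prec <- 1 / prior$s1^2 + J / v1
      mu1 <- stats::rnorm(1, (prior$m1 / prior$s1^2 + sum(g1) / v1) / prec,
                          sqrt(1 / prec))
      v1 <- 1 / stats::rgamma(1, prior$a1 + J / 2,
                              prior$b1 + sum((g1 - mu1)^2) / 2)
      prec <- 1 / prior$s2^2 + J / v2
      mu2 <- stats::rnorm(1, (prior$m2 / prior$s2^2 + sum(h2) / v2) / prec,
                          sqrt(1 / prec))
      v2 <- 1 / stats::rgamma(1, prior$a2 + J / 2,
                              prior$b2 + sum((h2 - mu2)^2) / 2)
      if (it <= n_burn && it %% 50 == 0) {
        delta <- min(0.25, 1 / sqrt(it / 50))
        ls1 <- ls1 + delta * (a1c / pmax(n1c, 1) - config$target_accept)
        ls2 <- ls2 + delta * (a2c / pmax(n2c, 1) - config$target_accept)
        a1c[] <- n1c[] <- 0; a2c[] <- n2c[] <- 0
      }
      if (it > n_burn) {
        i <- it - n_burn
        d_g1[i, ] <- g1; d_h2[i, ] <- h2
        d_hyp[i, ] <- c(mu1, sqrt(v1), mu2, sqrt(v2))
      }
    }
    chains[[ch]] <- list(g1 = d_g1, h2 = d_h2, hyp = d_hyp)
  }

  g1_all <- do.call(rbind, lapply(chains, `[[`, "g1"))
  h2_all <- do.call(rbind, lapply(chains, `[[`, "h2"))
  gam2_all <- if (lognorm) exp(h2_all) else h2_all
  z1 <- sweep(g1_all, 2, off, `+`)
  pi1 <- stats::plogis(z1)
  pi2 <- stats::plogis(z1 - gam2_all)
  out <- data.frame(
    indication = data$labels,
    selected = data$D,
    pi1_mean = colMeans(pi1),
    pi1_lo = apply(pi1, 2, stats::quantile, 0.025, names = FALSE),
    pi1_hi = apply(pi1, 2, stats::quantile, 0.975, names = FALSE),
    pi2_mean = colMeans(pi2),
    pi2_lo = apply(pi2, 2, stats::quantile, 0.025, names = FALSE),
    pi2_hi = apply(pi2, 2, stats::quantile, 0.975, names = FALSE),
    pr_pi1_gt_pi0 = colMeans(g1_all > 0),
    pr_pi2_gt_pi0 = colMeans(z1 - gam2_all > stats::qlogis(data$pi0)[col(z1)]),
    pr_pi1_gt_pi2 = colMeans(gam2_all > 0),
    stringsAsFactors = FALSE)
  diag_rows <- do.call(rbind, lapply(seq_len(J), function(j) {
    m <- vapply(chains, function(cc) cc$g1[, j], numeric(n_keep))
    data.frame(quantity = paste0("gamma1_", j),
               rhat = .split_rhat(m), ess = .ess(m))
  }))
  attr(out, "diagnostics") <- diag_rows
  attr(out, "draws") <- list(pi1 = pi1, pi2 = pi2, gamma1 = g1_all,
                             gamma2 = gam2_all)
  class(out) <- c("mats_summary", "data.frame")
  out
}

#' Stage-2 selection from interim exceedance probabilities
#'
#' Indication j is selected for the stage-2 randomized comparison when its
#' interim posterior probability that the high dose beats the reference
#' rate is at least the selection threshold.
#'
#' @param prob numeric vector of \eqn{\Pr(\pi_{1j} > \pi_{0j} \mid
#'   \mathrm{stage\text{-}1\ data})}, or a `mats_summary` (its
#'   `pr_pi1_gt_pi0` column is used).
#' @param threshold selection threshold in \eqn{[0, 1]}.
#' @return Logical selection flags `D`.
#' @examples
#' mats_select(c(0.9, 0.3, 0.7), 0.5)
#' @export
mats_select <- function(prob, threshold) {
  if (inherits(prob, "mats_summary")) prob <- prob$pr_pi1_gt_pi0
  stopifnot(threshold >= 0, threshold <= 1)
  prob >= threshold
}

# interim exceedance under an independent Beta(1,1) posterior per
# indication: deterministic in y, which keeps simulated selection
# enumerable exactly
.beta_exceed <- function(y, n, pi0) 1 - stats::pbeta(pi0, y + 1, n - y + 1)

#' Simulate a MATS trial
#'
#' Stage-1 responses are binomial draws for the high dose in every
#' indication; the interim selection rule is applied; stage-2 responses are
#' then drawn for both doses in the selected indications only.
#'
#' The default interim rule selects indication j when the posterior
#' probability \eqn{\Pr(\pi_{1j} > \pi_{0j})} under an independent
#' Beta(1,1) prior meets the threshold - a deterministic function of the
#' stage-1 count, so its operating characteristics can be enumerated
#' exactly. A custom `select_fun(y, n, pi0)` returning per-indication
#' probabilities may be supplied (e.g. a hierarchical interim fit).
#'
#' @param pi1_true,pi2_true true response rates per indication for the
#'   high and low dose.
#' @param pi0 reference rate(s).
#' @param n1_stage1 stage-1 patients per indication (high dose).
#' @param n_stage2 stage-2 patients per arm (both doses).
#' @param threshold interim selection threshold.
#' @param seed integer seed.
#' @param select_fun optional interim probability function.
#' @return A [mats_data].
#' @export
simulate_mats <- function(pi1_true, pi2_true, pi0, n1_stage1, n_stage2,
                          threshold, seed, select_fun = .beta_exceed) {
  J <- length(pi1_true)
  stopifnot(length(pi2_true) == J, all(pi1_true >= 0), all(pi1_true <= 1),
            all(pi2_true >= 0), all(pi2_true <= 1))
  if (length(pi0) == 1L) pi0 <- rep(pi0, J)
  set.seed(as.integer(seed))
  y11 <- stats::rbinom(J, n1_stage1, pi1_true)
  prob <- select_fun(y11, rep(n1_stage1, J), pi0)
  D <- mats_select(prob, threshold)
  rows <- data.frame(dose = 1, indication = seq_len(J), stage = 1,
                     y = y11, n = n1_stage1)
  for (j in which(D)) {
    y12 <- stats::rbinom(1, n_stage2, pi1_true[j])
    y22 <- stats::rbinom(1, n_stage2, pi2_true[j])
    rows <- rbind(rows,
                  data.frame(dose = 1, indication = j, stage = 2,
                             y = y12, n = n_stage2),
                  data.frame(dose = 2, indication = j, stage = 2,
                             y = y22, n = n_stage2))
  }
  mats_data(rows, pi0, selected = D)
}
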