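#' Enumerate set partitions of J baskets
#'
#' All partitions of \eqn{\{1, \dots, J\}} in canonical order (restricted
#' growth strings, lexicographic). The number of partitions is the Bell
#' number \eqn{B_J}, which governs the cost of partition-based model
#' averaging.
#'
#' @param J number of baskets, 1..12.
#' @return A list of partitions; each partition is a list of integer
#'   vectors (the subsets, in order of their smallest element).
#' @examples
#' enumerate_partitions(3)  # 5 partitions
#' @export
enumerate_partitions <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || J < 1 || J > 12 || J != round(J))
    stop("J must be an integer between 1 and 12 (partition counts grow as Bell numbers)")
  J <- as.integer(J)
  out <- list()
  rgs <- integer(J)
  recurse <- function(i, mx) {
    if (i > J) {
      part <- lapply(0:mx, function(k) which(rgs == k))
      out[[length(out) + 1L]] <<- part
      return(invisible(NULL))
    }
    for (a in 0:(mx + 1L)) {
      rgs[i] <<- a
      recurse(i + 1L, max(mx, a))
    }
  }
  rgs[1] <- 0L
  recurse(2L, 0L)
  out
}

# quadrature for one pooled subset: all baskets in the subset share one
# gamma with a N(mu0, sd0^2) prior; returns the log marginal likelihood and
# the normalized density of gamma on the grid gg, with edge atoms
.subset_quad <- function(y, n, off, mu0, sd0, cut, gg, nq = 32) {
  lc <- sum(lchoose(n, y))
  f_eval <- function(g) {
    vapply(g, function(gi) {
      z <- gi + off
      lc + sum(y * z - n * .log1pexp(z)) +
        stats::dnorm(gi, mu0, sd0, log = TRUE)
    }, numeric(1))
  }
  # Newton for the concave conditional mode
  m <- mu0
  for (it in 1:60) {
    p <- stats::plogis(m + off)
    g1 <- sum(y - n * p) - (m - mu0) / sd0^2
    g2 <- -sum(n * p * (1 - p)) - 1 / sd0^2
    step <- max(min(-g1 / g2, 4), -4)
    m <- m + step
    if (abs(step) < 1e-10) break
  }
  p <- stats::plogis(m + off)
  s <- 1 / sqrt(sum(n * p * (1 - p)) + 1 / sd0^2)
  lo <- min(m - 8 * s, mu0 - 7 * sd0)
  hi <- max(m + 8 * s, mu0 + 7 * sd0)
  br <- sort(c(lo, max(min(cut, hi), lo),
               max(min(m - 8 * s, hi), lo), max(min(m + 8 * s, hi), lo), hi))
  gl <- .gl_nodes(nq)
  fm <- f_eval(m)
  Z <- 0; above <- 0
  for (pn in 1:4) {
    a <- br[pn]; b <- br[pn + 1]
    if (b - a <= 0) next
    gz <- (a + b) / 2 + (b - a) / 2 * gl$x
    pz <- (b - a) / 2 * sum(gl$w * exp(f_eval(gz) - fm))
    Z <- Z + pz
    if (a >= cut - 1e-12) above <- above + pz
  }
  logZ <- fm + log(Z)
  dens <- exp(f_eval(gg) - logZ)
  list(logZ = logZ, frac_above = min(max(above / Z, 0), 1), dens = dens)
}

#' Bayesian model averaging over basket partitions
#'
#' Enumerates all set partitions of the baskets. Conditional on a
#' partition, baskets in the same subset share a single transformed effect
#' with a normal prior, pooling their data; baskets in different subsets do
#' not communicate. Partition posterior weights are proportional to the
#' partition prior times the marginal likelihood (each subset integral
#' computed by one-dimensional quadrature), and every reported quantity is
#' the weight-averaged mixture over partitions - a data-driven compromise
#' between complete pooling and stratified analysis.
#'
#' @param data a [basket_data]; at most 10 baskets (the partition count is
#'   the Bell number).
#' @param model a [model_spec] with a `partition_bma` prior and a real
#'   transformation, e.g.
#'   `model_spec(transform_spec("logit_increment"), partition_bma())`.
#' @param grid a [grid_config]; only the inner-integral settings are used.
#' @return A `posterior_summary` whose `$partition_weights` is a data frame
#'   of partitions (in [enumerate_partitions()] order) with prior and
#'   posterior weights.
#' @examples
#' d <- basket_data(NULL, y = c(6, 6, 1), n = c(20, 20, 20), pi0 = 0.2)
#' fit_bma(d, model_spec(transform_spec("logit_increment"), partition_bma()))
#' @export
fit_bma <- function(data, model, grid = grid_config()) {
  stopifnot(inherits(data, "basket_data"), inherits(model, "model_spec"))
  prior <- model$prior
  if (prior$family != "partition_bma")
    stop("fit_bma requires a partition_bma prior")
  J <- length(data$y)
  if (J > 10)
    stop(sprintf("J = %d gives %.0f partitions; partition averaging is limited to J <= 10",
                 J, .bell_number(J)))
  off <- .gamma_offset(model$transform, data$pi0)
  cut <- .gamma_cut(model$transform, data$pi0)
  gg <- seq(grid$gamma_range[1], grid$gamma_range[2],
            length.out = grid$gamma_points)

  parts <- enumerate_partitions(J)
  L <- length(parts)

  # distinct subsets are shared across partitions: cache their quadratures.
  # a subset's exceedance cut is checked to be common across its members.
  cache <- new.env(parent = emptyenv())
  subset_q <- function(S) {
    key <- paste(S, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    cS <- unique(cut[S])
    if (length(cS) > 1L)
      stop("baskets pooled in one subset must share a common exceedance cutoff; ",
           "use the logit_increment transform for differential reference rates")
    q <- .subset_quad(data$y[S], data$n[S], off[S], prior$within_mean,
                      prior$within_sd, cS, gg, nq = grid$panel_nodes)
    cache[[key]] <- q
    q
  }

  lp <- numeric(L)
  for (l in seq_len(L)) {
    lp[l] <- -prior$lambda * length(parts[[l]]) +
      sum(vapply(parts[[l]], function(S) subset_q(S)$logZ, numeric(1)))
  }
  prior_w <- exp(-prior$lambda * vapply(parts, length, integer(1)))
  prior_w <- prior_w / sum(prior_w)
  w <- exp(lp - max(lp)); w <- w / sum(w)

  # accumulate, per basket, the mixture over the subsets that contain it
  prob_exceed <- numeric(J)
  dens <- matrix(0, length(gg), J)
  for (l in seq_len(L)) {
    for (S in parts[[l]]) {
      q <- subset_q(S)
      prob_exceed[S] <- prob_exceed[S] + w[l] * q$frac_above
      dens[, S] <- dens[, S] + w[l] * q$dens
    }
  }
  post_mean_pi <- ci_low <- ci_high <- numeric(J)
  for (j in seq_len(J)) {
    sm <- .density_summaries(gg, dens[, j], off[j])
    post_mean_pi[j] <- sm$mean; ci_low[j] <- sm$q[1]; ci_high[j] <- sm$q[2]
  }

  pw <- data.frame(
    partition = vapply(parts, function(p)
      paste(vapply(p, function(S) paste0("{", paste(S, collapse = ","), "}"),
                   character(1)), collapse = ""), character(1)),
    n_subsets = vapply(parts, length, integer(1)),
    prior_weight = prior_w, posterior_weight = w,
    stringsAsFactors = FALSE)

  new_posterior_summary(labels = data$labels, prob_exceed = prob_exceed,
                        post_mean_pi = post_mean_pi, ci_low = ci_low,
                        ci_high = ci_high, method = "bma",
                        partition_weights = pw,
                        log_marginal = max(lp) + log(sum(exp(lp - max(lp)))))
}

# Bell numbers by the Bell-triangle recurrence
.bell_number <- function(J) {
  row <- 1
  for (i in seq_len(J - 1)) {
    new <- numeric(i + 1)
    new[1] <- row[length(row)]
    for (k in seq_len(i)) new[k + 1] <- new[k] + row[k]
    row <- new
  }
  row[length(row)]
}
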