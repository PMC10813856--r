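# Operating-characteristics machinery: trial simulation under scenarios,
# error/power summaries, and weak/strong FWER threshold calibration.
#
# The default per-replicate posterior engine is the deterministic
# quadrature grid, which removes sampler noise from threshold estimation.
# Because the conditional per-basket integrals depend only on (y, n, pi0,
# cutoff) and the grid - not on the hyperprior - they are precomputed once
# per sample size and shared across replicates, scenarios and priors.

.bb_cache <- new.env(parent = emptyenv())

.grid_key <- function(grid) {
  paste(c(grid$mu_range, grid$mu_points, grid$sigma_range,
          grid$sigma_points, grid$panel_nodes), collapse = "|")
}

# precomputed conditional tables for all y = 0..n at fixed (n, pi0, cut):
# logL[y+1, cell] and R[y+1, cell] = P(gamma > cut | y, cell)
.cond_tables <- function(cells, grid, n, pi0, cut, transform) {
  key <- paste("tab", .grid_key(grid), length(cells$mu), n,
               signif(pi0, 12), signif(cut, 12), transform$kind, sep = "|")
  got <- .bb_cache[[key]]
  if (!is.null(got)) return(got)
  off <- .gamma_offset(transform, pi0)
  C <- length(cells$mu)
  logL <- matrix(0, n + 1, C)
  R <- matrix(0, n + 1, C)
  for (y in 0:n) {
    q <- .cond_quad(y, n, off, cut, cells$mu, cells$sigma, nq = grid$panel_nodes)
    logL[y + 1, ] <- q$logZ
    R[y + 1, ] <- q$frac_above
  }
  out <- list(logL = logL, R = R)
  .bb_cache[[key]] <- out
  out
}

# exceedance probabilities for many replicate datasets sharing a common
# per-basket design (n_j, pi0_j, cut_j). Y is reps x J.
.exceed_matrix <- function(model, Y, n, pi0, cut, grid) {
  J <- ncol(Y)
  n <- rep_len(n, J); pi0 <- rep_len(pi0, J); cut <- rep_len(cut, J)
  cells <- .prior_cells(model$prior, grid)
  C <- length(cells$mu)
  tabs <- lapply(seq_len(J), function(j)
    .cond_tables(cells, grid, n[j], pi0[j], cut[j], model$transform))
  reps <- nrow(Y)
  pe <- matrix(0, reps, J)
  if (C == 1L) {
    for (j in seq_len(J)) pe[, j] <- tabs[[j]]$R[Y[, j] + 1, 1]
    return(pe)
  }
  lw <- cells$lw
  for (r in seq_len(reps)) {
    lp <- lw
    for (j in seq_len(J)) lp <- lp + tabs[[j]]$logL[Y[r, j] + 1, ]
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    for (j in seq_len(J)) pe[r, j] <- sum(w * tabs[[j]]$R[Y[r, j] + 1, ])
  }
  pe
}

#' Design specification for operating-characteristics simulation
#'
#' @param model a [model_spec].
#' @param rule a [decision_rule], or `NULL` before calibration.
#' @param n_per_basket patients per basket at the final analysis.
#' @param interim optional [interim_rule] for futility stopping.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(model, rule = NULL, n_per_basket = 20, interim = NULL) {
  stopifnot(inherits(model, "model_spec"),
            is.null(rule) || inherits(rule, "decision_rule"),
            n_per_basket >= 1,
            is.null(interim) || inherits(interim, "interim_rule"))
  if (!is.null(interim) && any(interim$looks >= n_per_basket))
    stop("interim looks must occur before the final sample size")
  structure(list(model = model, rule = rule,
                 n_per_basket = as.integer(n_per_basket), interim = interim),
            class = "design_spec")
}

#' Simulate one basket trial under a scenario
#'
#' Responders are drawn independently per basket,
#' \eqn{y_j \sim \mathrm{Bin}(n, \pi_{\mathrm{true},j})}; reference rates
#' are copied from the scenario.
#'
#' @param scenario a [scenario].
#' @param n_per_basket patients per basket.
#' @param seed integer seed for the draw.
#' @return A [basket_data].
#' @examples
#' simulate_trial(scenario("null", rep(0.2, 4), 0.2), 20, seed = 1)
#' @export
simulate_trial <- function(scenario, n_per_basket, seed) {
  stopifnot(inherits(scenario, "scenario"))
  set.seed(as.integer(seed))
  y <- stats::rbinom(length(scenario$pi_true), n_per_basket, scenario$pi_true)
  basket_data(paste0("basket_", seq_along(y)), y,
              rep(n_per_basket, length(y)), scenario$pi0)
}

# patient-level uniform draws: reps x J x n array; thresholding at the true
# rates gives binomial responses with common random numbers across
# scenarios and design variants
.sim_uniforms <- function(reps, J, n, seed) {
  set.seed(as.integer(seed))
  array(stats::runif(reps * J * n), dim = c(reps, J, n))
}

.responses_from_uniforms <- function(U, pi_true, n_at = dim(U)[3]) {
  J <- dim(U)[2]
  vapply(seq_len(J), function(j)
    rowSums(U[, j, seq_len(n_at), drop = FALSE] < pi_true[j]), numeric(dim(U)[1]))
}

.pct_se <- function(p, reps) 100 * sqrt(p * (1 - p) / reps)

.make_oc_result <- function(scenario, reject, stopped = NULL, n_acc = NULL) {
  reps <- nrow(reject)
  prom <- scenario$promising
  reject_pct <- 100 * colMeans(reject)
  fwer <- if (any(!prom)) 100 * mean(apply(reject[, !prom, drop = FALSE], 1, any))
          else NA_real_
  fwp_d <- if (any(prom)) 100 * mean(apply(reject[, prom, drop = FALSE], 1, any))
           else NA_real_
  fwp_c <- if (any(prom)) 100 * mean(apply(reject[, prom, drop = FALSE], 1, all))
           else NA_real_
  # structural orderings hold by construction; assert them on every run
  if (any(prom)) {
    stopifnot(fwp_c <= min(reject_pct[prom]) + 1e-9,
              fwp_d >= max(reject_pct[prom]) - 1e-9)
  }
  if (any(!prom)) stopifnot(fwer >= max(reject_pct[!prom]) - 1e-9)
  structure(list(scenario = scenario$name,
                 promising = prom,
                 reject_pct = reject_pct,
                 reject_se = .pct_se(reject_pct / 100, reps),
                 FWER = fwer, FWER_se = if (is.na(fwer)) NA_real_ else .pct_se(fwer / 100, reps),
                 FWP_D = fwp_d, FWP_D_se = if (is.na(fwp_d)) NA_real_ else .pct_se(fwp_d / 100, reps),
                 FWP_C = fwp_c, FWP_C_se = if (is.na(fwp_c)) NA_real_ else .pct_se(fwp_c / 100, reps),
                 expected_n = if (is.null(n_acc)) NULL else colMeans(n_acc),
                 stop_pct = if (is.null(stopped)) NULL else 100 * colMeans(stopped),
                 reps = reps),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Operating characteristics, scenario '%s' (%d replicates)\n",
              x$scenario, x$reps))
  cat("  reject %:", paste(sprintf("%.1f", x$reject_pct), collapse = "  "), "\n")
  if (!is.na(x$FWER)) cat(sprintf("  FWER: %.1f%% (SE %.1f)\n", x$FWER, x$FWER_se))
  if (!is.na(x$FWP_D)) cat(sprintf("  FWP-D: %.1f%%  FWP-C: %.1f%%\n", x$FWP_D, x$FWP_C))
  if (!is.null(x$expected_n))
    cat("  expected n:", paste(sprintf("%.1f", x$expected_n), collapse = "  "), "\n")
  invisible(x)
}

# exceedance matrix for a design under a scenario, given a patient-level
# uniform array (handles interim futility; returns rejection matrix too)
.run_design <- function(design, scenario, U, grid) {
  reps <- dim(U)[1]; J <- dim(U)[2]
  model <- design$model
  n_final <- design$n_per_basket
  cut0 <- .gamma_cut(model$transform, scenario$pi0)
  if (is.null(design$interim)) {
    Y <- .responses_from_uniforms(U, scenario$pi_true, n_final)
    pe <- .exceed_matrix(model, Y, n_final, scenario$pi0, cut0, grid)
    return(list(pe = pe, stopped = NULL, n_acc = NULL))
  }
  ir <- design$interim
  pit0 <- rep_len(ir$pi_tilde0, J)
  # futility exceedance is against pi_tilde0: cutoff on the gamma scale
  cut_f <- vapply(seq_len(J), function(j)
    forward_transform(model$transform, pit0[j], scenario$pi0[j]), numeric(1))
  stopped <- matrix(FALSE, reps, J)
  n_acc <- matrix(n_final, reps, J)
  y_frozen <- matrix(0L, reps, J)
  for (r_look in seq_along(ir$looks)) {
    n_at <- ir$looks[r_look]
    Y_at <- .responses_from_uniforms(U, scenario$pi_true, n_at)
    # accrued data: frozen counts for already-stopped baskets
    Yc <- Y_at; Nc <- matrix(n_at, reps, J)
    Yc[stopped] <- y_frozen[stopped]; Nc[stopped] <- n_acc[stopped]
    cthr <- .interim_c(ir, r_look, J)
    pe_f <- .exceed_mixed(model, Yc, Nc, scenario$pi0, cut_f, grid)
    newly <- (pe_f < matrix(cthr, reps, J, byrow = TRUE)) & !stopped
    y_frozen[newly] <- Y_at[newly]
    n_acc[newly] <- n_at
    stopped <- stopped | newly
  }
  Y_fin <- .responses_from_uniforms(U, scenario$pi_true, n_final)
  Y_fin[stopped] <- y_frozen[stopped]
  N_fin <- matrix(n_final, reps, J); N_fin[stopped] <- n_acc[stopped]
  pe <- .exceed_mixed(model, Y_fin, N_fin, scenario$pi0, cut0, grid)
  list(pe = pe, stopped = stopped, n_acc = n_acc)
}

# exceedance when sample sizes differ across replicates/baskets (interim
# stopping freezes some baskets at an earlier look)
.exceed_mixed <- function(model, Y, N, pi0, cut, grid) {
  J <- ncol(Y)
  pi0 <- rep_len(pi0, J); cut <- rep_len(cut, J)
  cells <- .prior_cells(model$prior, grid)
  C <- length(cells$mu)
  n_distinct <- sort(unique(as.vector(N)))
  tabs <- list()
  for (n in n_distinct) for (j in seq_len(J)) {
    key <- paste(n, j)
    if (any(N[, j] == n) && is.null(tabs[[key]]))
      tabs[[key]] <- .cond_tables(cells, grid, n, pi0[j], cut[j], model$transform)
  }
  reps <- nrow(Y)
  pe <- matrix(0, reps, J)
  for (r in seq_len(reps)) {
    if (C == 1L) {
      for (j in seq_len(J))
        pe[r, j] <- tabs[[paste(N[r, j], j)]]$R[Y[r, j] + 1, 1]
      next
    }
    lp <- cells$lw
    for (j in seq_len(J)) lp <- lp + tabs[[paste(N[r, j], j)]]$logL[Y[r, j] + 1, ]
    w <- exp(lp - max(lp)); w <- w / sum(w)
    for (j in seq_len(J)) pe[r, j] <- sum(w * tabs[[paste(N[r, j], j)]]$R[Y[r, j] + 1, ])
  }
  pe
}

#' Frequentist operating characteristics of a Bayesian basket design
#'
#' Simulates `reps` trials under a scenario, fits the design's borrowing
#' model to each (deterministic quadrature engine by default), applies the
#' posterior-probability decision rule, and reports relative frequencies:
#' per-basket rejection percentage, family-wise error rate (any true-null
#' rejection; reported when the scenario contains a null basket),
#' disjunctive power FWP-D (any promising basket rejected) and conjunctive
#' power FWP-C (all promising baskets rejected), each with its binomial
#' Monte-Carlo standard error. With an interim futility rule the expected
#' accrual per basket is also reported, and a stopped basket cannot be
#' declared promising at the final analysis.
#'
#' @param design a [design_spec] with a non-`NULL` rule.
#' @param scenario a [scenario].
#' @param reps number of simulated trials.
#' @param seed integer seed.
#' @param grid a [grid_config] for the quadrature engine.
#' @return An object of class `oc_result`.
#' @examples
#' \donttest{
#' des <- design_spec(named_prior("prior_I"), decision_rule(0.982), 20)
#' operating_characteristics(des, scenario("null", rep(0.2, 4), 0.2),
#'                           reps = 200, seed = 1)
#' }
#' @export
operating_characteristics <- function(design, scenario, reps, seed,
                                      grid = grid_config()) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "scenario"),
            reps >= 1)
  if (is.null(design$rule)) stop("design has no decision rule; calibrate first")
  J <- length(scenario$pi_true)
  U <- .sim_uniforms(reps, J, design$n_per_basket, seed)
  run <- .run_design(design, scenario, U, grid)
  q <- design$rule$q
  if (length(q) == 1L) q <- rep(q, J)
  reject <- sweep(run$pe, 2, q, `>`)
  if (!is.null(run$stopped)) reject <- reject & !run$stopped
  .make_oc_result(scenario, reject, run$stopped, run$n_acc)
}

# smallest threshold on the grid whose empirical FWER is <= alpha, given
# the per-replicate maxima of the null-basket exceedance probabilities
.smallest_q <- function(T_max, alpha, step) {
  qgrid <- seq(0, 1 - step, by = step)
  n_exc <- vapply(qgrid, function(q) mean(T_max > q), numeric(1))
  ok <- which(n_exc <= alpha)
  if (length(ok) == 0) return(NA_real_)
  qgrid[ok[1]]
}

#' Calibrate the decision threshold for weak FWER control
#'
#' Simulates the global null scenario, fits the borrowing model to every
#' replicate, and returns the empirical \eqn{(1-\alpha)} quantile of the
#' per-trial maximum exceedance probability, rounded up to the threshold
#' grid: the smallest grid value `q` with
#' \eqn{\#\{\max_j \Pr(\pi_j > \pi_{0j}) > q\} / \mathrm{reps} \le \alpha}
#' (ties resolved toward smaller `q`, i.e. toward attaining rather than
#' undershooting the target level). Using the same threshold for all
#' baskets, the returned value yields empirical FWER at most `alpha` on the
#' calibration replicates.
#'
#' @param design a [design_spec]; its rule, if any, is ignored.
#' @param global_null a [scenario] with no promising basket.
#' @param alpha target family-wise error rate.
#' @param reps simulated null trials.
#' @param seed integer seed.
#' @param step threshold grid resolution.
#' @param grid a [grid_config].
#' @return A list with the calibrated threshold `q`, the achieved FWER on
#'   the calibration set, the per-trial maxima `T_max`, and the settings.
#' @examples
#' \donttest{
#' des <- design_spec(named_prior("prior_I"), NULL, 20)
#' calibrate_weak(des, scenario("null", rep(0.2, 4), 0.2),
#'                reps = 200, seed = 1)$q
#' }
#' @export
calibrate_weak <- function(design, global_null, alpha = 0.05, reps = 1000,
                           seed, step = 0.001, grid = grid_config()) {
  stopifnot(inherits(design, "design_spec"), inherits(global_null, "scenario"))
  if (any(global_null$promising))
    stop("weak calibration requires a global null scenario (no promising basket)")
  if (alpha * reps < 5)
    warning("alpha * reps < 5: the calibrated quantile will be unstable")
  J <- length(global_null$pi_true)
  U <- .sim_uniforms(reps, J, design$n_per_basket, seed)
  Y <- .responses_from_uniforms(U, global_null$pi_true)
  cut <- .gamma_cut(design$model$transform, global_null$pi0)
  pe <- .exceed_matrix(design$model, Y, design$n_per_basket,
                       global_null$pi0, cut, grid)
  T_max <- apply(pe, 1, max)
  q <- .smallest_q(T_max, alpha, step)
  list(q = q, mode = "weak", achieved_fwer = mean(T_max > q),
       T_max = T_max, alpha = alpha, reps = reps, seed = seed, step = step)
}

#' Calibrate the decision threshold for strong FWER control
#'
#' Finds the smallest common threshold (on the grid) whose empirical FWER
#' is at most `alpha` in every supplied scenario that contains at least one
#' null basket. Common random numbers are used: the same patient-level
#' uniform draws generate the replicate data in every scenario and for
#' every candidate threshold, so the comparison across thresholds is paired
#' and the empirical FWER is exactly non-increasing in the threshold.
#'
#' @param design a [design_spec]; its rule, if any, is ignored.
#' @param scenarios a list of [scenario] objects (scenarios with no null
#'   basket impose no constraint).
#' @inheritParams calibrate_weak
#' @return A list with the threshold `q`, the mode, and per-scenario
#'   achieved FWER at `q`.
#' @export
calibrate_strong <- function(design, scenarios, alpha = 0.05, reps = 1000,
                             seed, step = 0.001, grid = grid_config()) {
  stopifnot(inherits(design, "design_spec"), length(scenarios) >= 1)
  J <- length(scenarios[[1]]$pi_true)
  U <- .sim_uniforms(reps, J, design$n_per_basket, seed)
  per_scn <- list()
  q_all <- 0
  for (s in scenarios) {
    stopifnot(inherits(s, "scenario"))
    nulls <- which(!s$promising)
    if (length(nulls) == 0) next
    Y <- .responses_from_uniforms(U, s$pi_true)
    cut <- .gamma_cut(design$model$transform, s$pi0)
    pe <- .exceed_matrix(design$model, Y, design$n_per_basket, s$pi0, cut, grid)
    T_max <- apply(pe[, nulls, drop = FALSE], 1, max)
    q_s <- .smallest_q(T_max, alpha, step)
    per_scn[[s$name]] <- list(q = q_s, T_max = T_max)
    q_all <- max(q_all, q_s)
  }
  if (length(per_scn) == 0)
    stop("no scenario contains a null basket; nothing to control")
  achieved <- vapply(per_scn, function(p) mean(p$T_max > q_all), numeric(1))
  list(q = q_all, mode = "strong",
       achieved_fwer = achieved, alpha = alpha, reps = reps,
       seed = seed, step = step)
}

#' Operating-characteristics table across design variants and scenarios
#'
#' One row per (scenario, variant) with per-basket rejection percentages,
#' FWER, disjunctive and conjunctive family-wise power, and Monte-Carlo
#' standard errors. Common random numbers are used across variants by
#' default so comparisons are paired.
#'
#' @param variants named list of [design_spec] objects (with rules).
#' @param scenarios list of [scenario] objects.
#' @param reps replicates per cell.
#' @param seed integer seed.
#' @param crn share simulated datasets across variants (default `TRUE`).
#' @param grid a [grid_config].
#' @return A data frame; also carries the `oc_result` objects in
#'   `attr(, "results")`.
#' @export
oc_table <- function(variants, scenarios, reps, seed, crn = TRUE,
                     grid = grid_config()) {
  stopifnot(length(variants) >= 1, length(scenarios) >= 1)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant_", seq_along(variants))
  rows <- list(); results <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    J <- length(s$pi_true)
    for (vi in seq_along(variants)) {
      v <- variants[[vi]]
      seed_v <- if (crn) .substream(seed, si) else .substream(seed, si * 1000 + vi)
      res <- operating_characteristics(v, s, reps, seed_v, grid)
      results[[paste(s$name, names(variants)[vi], sep = " / ")]] <- res
      row <- data.frame(scenario = s$name, borrowing = names(variants)[vi],
                        stringsAsFactors = FALSE)
      for (j in seq_len(J)) row[[paste0("reject_pct_", j)]] <- res$reject_pct[j]
      row$FWER <- res$FWER; row$FWP_D <- res$FWP_D; row$FWP_C <- res$FWP_C
      for (j in seq_len(J)) row[[paste0("se_", j)]] <- res$reject_se[j]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
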