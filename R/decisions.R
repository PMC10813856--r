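#' Posterior-probability decision rule
#'
#' A basket is declared promising when its posterior exceedance probability
#' strictly exceeds its threshold:
#' \eqn{\Pr(\pi_j > \pi_{0j} \mid \mathrm{data}) > q_j}.
#'
#' @param q threshold(s) in (0, 1); a scalar is shared by all baskets.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("thresholds q must lie strictly in (0,1)")
  structure(list(q = as.numeric(q)), class = "decision_rule")
}

#' Apply a decision rule to a posterior summary
#'
#' @param summary a `posterior_summary` (or a numeric vector of exceedance
#'   probabilities).
#' @param rule a [decision_rule].
#' @return Logical rejection flag per basket; `TRUE` means the null
#'   hypothesis \eqn{\pi_j \le \pi_{0j}} is rejected. The inequality is
#'   strict: a probability exactly equal to the threshold does not reject.
#' @examples
#' decide(c(0.99, 0.5), decision_rule(0.982))
#' @export
decide <- function(summary, rule) {
  stopifnot(inherits(rule, "decision_rule"))
  pe <- if (inherits(summary, "posterior_summary")) summary$prob_exceed
        else as.numeric(summary)
  q <- rule$q
  if (length(q) == 1L) q <- rep(q, length(pe))
  if (length(q) != length(pe)) stop("threshold and summary dimensions differ")
  pe > q
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact equal-tailed interval from beta quantiles:
#' lower \eqn{= \mathrm{qbeta}(\alpha/2;\, y,\, n-y+1)} (0 when `y = 0`),
#' upper \eqn{= \mathrm{qbeta}(1-\alpha/2;\, y+1,\, n-y)} (1 when `y = n`).
#' Guarantees at least nominal coverage for every true rate.
#'
#' @param y number of successes.
#' @param n number of trials, >= 1.
#' @param level confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` (a 2-column matrix for vector
#'   input).
#' @examples
#' clopper_pearson(2, 15)
#' @export
clopper_pearson <- function(y, n, level = 0.95) {
  if (any(n < 1)) stop("degenerate input: n must be at least 1")
  if (any(y < 0) || any(y > n)) stop("need 0 <= y <= n")
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lo <- ifelse(y == 0, 0, stats::qbeta(alpha / 2, y, n - y + 1))
  hi <- ifelse(y == n, 1, stats::qbeta(1 - alpha / 2, y + 1, n - y))
  if (length(y) == 1L) c(lower = lo, upper = hi)
  else cbind(lower = lo, upper = hi)
}

#' Stratified (no-borrowing) frequentist analysis
#'
#' Each basket analyzed on its own: point estimate \eqn{y_j / n_j} with an
#' exact Clopper-Pearson interval. No cross-basket dependence; permuting
#' the baskets permutes the output rows identically.
#'
#' @param data a [basket_data].
#' @param level confidence level.
#' @return A data frame with columns `basket`, `y`, `n`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @examples
#' stratified_analysis(basket_fixture("imatinib"))
#' @export
stratified_analysis <- function(data, level = 0.95) {
  stopifnot(inherits(data, "basket_data"))
  ci <- clopper_pearson(data$y, data$n, level)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1)
  data.frame(basket = data$labels, y = data$y, n = data$n,
             estimate = data$y / data$n,
             ci_low = ci[, 1], ci_high = ci[, 2],
             stringsAsFactors = FALSE)
}

#' Futility reference rate as the midpoint of null and target rates
#'
#' \eqn{\tilde\pi_{0j} = (\pi_{0j} + \pi_{1j}) / 2}: interim futility is
#' judged against a rate halfway between the reference and the target.
#'
#' @param pi0 reference rate(s).
#' @param pi1 target rate(s), strictly greater than `pi0`.
#' @return The midpoint rate(s).
#' @examples
#' midpoint_reference(0.2, 0.4)  # 0.3
#' @export
midpoint_reference <- function(pi0, pi1) {
  if (any(pi0 >= pi1)) stop("need pi0 < pi1")
  (pi0 + pi1) / 2
}

#' Interim futility rule
#'
#' At the r-th interim look, accrual in basket j halts when
#' \eqn{\Pr(\pi_j > \tilde\pi_{0j} \mid \mathrm{interim\ data}) < c_{jr}}
#' (strict inequality). Stopping is binding and basket-local: a stopped
#' basket accrues no further patients, and by default it cannot be declared
#' promising at the final analysis.
#'
#' @param pi_tilde0 futility reference rate per basket (often
#'   [midpoint_reference()]).
#' @param c stopping threshold(s) in (0, 1); a scalar, a vector per look,
#'   or a looks-by-baskets matrix.
#' @param looks strictly increasing per-basket patient counts at which
#'   interim analyses occur.
#' @return An object of class `interim_rule`.
#' @export
interim_rule <- function(pi_tilde0, c, looks) {
  if (any(!is.finite(c)) || any(c < 0) || any(c >= 1))
    stop("stopping thresholds must lie in [0,1)")
  looks <- as.integer(looks)
  if (length(looks) < 1 || any(diff(looks) <= 0) || any(looks < 1))
    stop("looks must be strictly increasing positive patient counts")
  structure(list(pi_tilde0 = as.numeric(pi_tilde0), c = c, looks = looks),
            class = "interim_rule")
}

.interim_c <- function(rule, look, J) {
  cc <- rule$c
  if (is.matrix(cc)) return(rep_len(cc[look, ], J))
  if (length(cc) == length(rule$looks)) return(rep(cc[look], J))
  rep_len(cc, J)
}

#' Apply the futility rule at an interim look
#'
#' The supplied summary must have been computed with the futility reference
#' \eqn{\tilde\pi_{0j}} substituted for the efficacy reference - i.e. its
#' `prob_exceed` is \eqn{\Pr(\pi_j > \tilde\pi_{0j} \mid \mathrm{data})}.
#'
#' @param interim_summary a `posterior_summary` (or exceedance vector)
#'   computed against `pi_tilde0`.
#' @param rule an [interim_rule].
#' @param look interim look index into `rule$looks`.
#' @return Logical per basket; `TRUE` means stop accrual for futility.
#' @examples
#' futility_check(c(0.04, 0.6), interim_rule(0.3, c = 0.05, looks = 10), 1)
#' @export
futility_check <- function(interim_summary, rule, look) {
  stopifnot(inherits(rule, "interim_rule"))
  if (look < 1 || look > length(rule$looks))
    stop("look index outside the interim schedule")
  pe <- if (inherits(interim_summary, "posterior_summary"))
    interim_summary$prob_exceed else as.numeric(interim_summary)
  pe < .interim_c(rule, look, length(pe))
}

#' Write a decision report
#'
#' One row per basket with the exceedance probability, threshold and
#' rejection flag, as CSV or JSON.
#'
#' @param summary a `posterior_summary`.
#' @param rule a [decision_rule].
#' @param path output path; format chosen by extension (`.json` or CSV
#'   otherwise).
#' @return The report data frame, invisibly.
#' @export
decision_report <- function(summary, rule, path = NULL) {
  rej <- decide(summary, rule)
  q <- rule$q
  if (length(q) == 1L) q <- rep(q, length(rej))
  rep_df <- data.frame(basket = summary$labels,
                       prob_exceed = summary$prob_exceed,
                       q = q, rejected = rej, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(rep_df, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    else utils::write.csv(rep_df, path, row.names = FALSE)
  }
  invisible(rep_df)
}
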