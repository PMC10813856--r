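#' Basket trial data
#'
#' Container for per-basket binomial response data in a basket trial:
#' responder counts `y`, sample sizes `n`, basket-specific reference
#' (standard-of-care) response rates `pi0`, and optionally target response
#' rates `pi1` used by interim futility rules. Reference rates are stored per
#' basket even when they are constant across baskets, so designs with
#' differential reference rates need no schema change. Basket order is
#' preserved everywhere: outputs are always reported in input order.
#'
#' @param labels character vector of basket names.
#' @param y integer vector, responders per basket.
#' @param n integer vector, patients per basket.
#' @param pi0 numeric vector (or scalar, recycled), reference rate per basket,
#'   strictly inside (0, 1).
#' @param pi1 optional numeric vector (or scalar), target rate per basket;
#'   must satisfy `pi0 < pi1 < 1` where supplied.
#'
#' @return An object of class `basket_data`: a list with fields `labels`,
#'   `y`, `n`, `pi0` and (possibly `NULL`) `pi1`.
#' @examples
#' basket_data(c("A", "B"), y = c(3, 5), n = c(20, 20), pi0 = 0.2)
#' @export
basket_data <- function(labels, y, n, pi0, pi1 = NULL) {
  J <- length(y)
  if (J < 1L) stop("need at least one basket")
  if (missing(labels) || is.null(labels)) labels <- paste0("basket_", seq_len(J))
  if (length(pi0) == 1L) pi0 <- rep(pi0, J)
  if (!is.null(pi1) && length(pi1) == 1L) pi1 <- rep(pi1, J)
  if (length(labels) != J || length(n) != J || length(pi0) != J)
    stop("labels, y, n, pi0 must have equal length")
  if (!is.null(pi1) && length(pi1) != J) stop("pi1 must match the number of baskets")
  y <- as.integer(round(y)); n <- as.integer(round(n))
  for (j in seq_len(J)) {
    if (is.na(y[j]) || is.na(n[j]) || n[j] < 1L)
      stop(sprintf("row %d (%s): n must be a positive count", j, labels[j]))
    if (y[j] < 0L || y[j] > n[j])
      stop(sprintf("row %d (%s): need 0 <= y <= n, got y=%d, n=%d", j, labels[j], y[j], n[j]))
    if (!is.finite(pi0[j]) || pi0[j] <= 0 || pi0[j] >= 1)
      stop(sprintf("row %d (%s): pi0 must lie strictly in (0,1)", j, labels[j]))
    if (!is.null(pi1)) {
      if (!is.finite(pi1[j]) || pi1[j] <= pi0[j] || pi1[j] >= 1)
        stop(sprintf("row %d (%s): need pi0 < pi1 < 1", j, labels[j]))
    }
  }
  structure(list(labels = as.character(labels), y = y, n = n,
                 pi0 = as.numeric(pi0), pi1 = if (is.null(pi1)) NULL else as.numeric(pi1)),
            class = "basket_data")
}

#' @export
print.basket_data <- function(x, ...) {
  cat(sprintf("Basket trial data: %d baskets, %d/%d responders overall (%.1f%%)\n",
              length(x$y), sum(x$y), sum(x$n), 100 * pooled_rate(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.basket_data <- function(x, ...) {
  d <- data.frame(basket = x$labels, y = x$y, n = x$n, pi0 = x$pi0,
                  stringsAsFactors = FALSE)
  if (!is.null(x$pi1)) d$pi1 <- x$pi1
  d
}

#' Read basket trial data from CSV
#'
#' Expects a header `basket,y,n,pi0` with an optional `pi1` column; rows are
#' kept in file order. Validation failures name the offending row.
#'
#' @param path path to a CSV file.
#' @return A [basket_data] object.
#' @export
load_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("basket", "y", "n", "pi0")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  basket_data(d$basket, d$y, d$n, d$pi0, pi1 = if ("pi1" %in% names(d)) d$pi1 else NULL)
}

#' Write basket trial data to CSV
#'
#' Round-trips bit-identically with [load_trial()] for the integer fields.
#'
#' @param data a [basket_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Overall (pooled) response rate
#'
#' Total responders over total patients across all baskets,
#' \eqn{\sum_j y_j / \sum_j n_j}. Invariant under permutation of baskets and
#' under merging baskets by summing their counts.
#'
#' @param data a [basket_data] object.
#' @return A single probability.
#' @examples
#' pooled_rate(basket_fixture("imatinib"))  # 28/179
#' @export
pooled_rate <- function(data) {
  stopifnot(inherits(data, "basket_data"))
  N <- sum(data$n)
  if (N <= 0) stop("degenerate input: total sample size is zero")
  sum(data$y) / N
}

#' Simulation scenario
#'
#' A named configuration of true response rates and reference rates per
#' basket. A basket is flagged promising exactly when its true rate exceeds
#' its reference rate.
#'
#' @param name scenario label.
#' @param pi_true numeric vector of true response rates in `[0, 1]`.
#' @param pi0 numeric vector (or scalar) of reference rates in (0, 1).
#' @return An object of class `scenario` with fields `name`, `pi_true`,
#'   `pi0` and the logical `promising` flags.
#' @examples
#' scenario("global null", pi_true = rep(0.2, 4), pi0 = 0.2)
#' @export
scenario <- function(name, pi_true, pi0) {
  J <- length(pi_true)
  if (length(pi0) == 1L) pi0 <- rep(pi0, J)
  if (length(pi0) != J) stop("pi_true and pi0 must have equal length")
  if (any(!is.finite(pi_true)) || any(pi_true < 0) || any(pi_true > 1))
    stop("pi_true must lie in [0,1]")
  if (any(pi0 <= 0) || any(pi0 >= 1)) stop("pi0 must lie strictly in (0,1)")
  structure(list(name = as.character(name), pi_true = as.numeric(pi_true),
                 pi0 = as.numeric(pi0), promising = pi_true > pi0),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': true rates (%s), reference rates (%s)\n",
              x$name, paste(x$pi_true, collapse = ", "),
              paste(x$pi0, collapse = ", ")))
  cat("  promising baskets:",
      if (any(x$promising)) paste(which(x$promising), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Bundled trial data and scenario fixtures
#'
#' Returns one of the bundled data sets shipped with the package:
#' \describe{
#'   \item{`imatinib`}{The 10-subtype advanced-sarcoma trial of imatinib
#'     (179 patients). The published analysis compared each subtype's
#'     response rate to a reference rate of 30\%, which is attached here as
#'     `pi0 = 0.30` for every basket.}
#'   \item{`vemurafenib`}{The 6-cohort BRAF V600 non-melanoma trial of
#'     vemurafenib (84 patients), with the published reference rate of 15\%
#'     attached as `pi0 = 0.15`.}
#'   \item{`scenarios`}{The six 4-basket simulation scenarios (global null,
#'     global alternative, and four mixed configurations) with all reference
#'     rates 20\%, returned as a list of [scenario] objects.}
#' }
#'
#' @param name one of `"imatinib"`, `"vemurafenib"`, `"scenarios"`.
#' @return A [basket_data] object, or a list of [scenario] objects.
#' @examples
#' basket_fixture("imatinib")
#' basket_fixture("scenarios")[[1]]
#' @export
basket_fixture <- function(name) {
  valid <- c("imatinib", "vemurafenib", "scenarios")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown fixture; valid names are: ", paste(valid, collapse = ", "))
  if (name == "scenarios") {
    path <- system.file("extdata", "scenarios.csv", package = "basketborrow",
                        mustWork = TRUE)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(lapply(seq_len(nrow(d)), function(i) {
      scenario(d$name[i],
               pi_true = as.numeric(d[i, grep("^pi_true", names(d))]),
               pi0 = as.numeric(d[i, grep("^pi0", names(d))]))
    }))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "basketborrow",
                      mustWork = TRUE)
  load_trial(path)
}
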