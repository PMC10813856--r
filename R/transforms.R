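#' Transformation of the basket response rate
#'
#' The transformation \eqn{\gamma_j = h(\pi_j)} selects *what* quantity is
#' borrowed across baskets:
#' \describe{
#'   \item{`identity`}{\eqn{h(\pi) = \pi}; the raw rates are assumed similar.}
#'   \item{`logit`}{\eqn{h(\pi) = \log\{\pi/(1-\pi)\}}; similar log odds.}
#'   \item{`logit_increment`}{\eqn{h(\pi) = \mathrm{logit}(\pi) -
#'     \mathrm{logit}(\pi_0)}; similar improvements over basket-specific
#'     reference rates, appropriate when reference rates differ.}
#'   \item{`hypothesis_indicator`}{\eqn{h(\pi) = 1(\pi > \pi_0)}; borrowing
#'     at the hypothesis level only. Many-to-one, hence not invertible.}
#' }
#'
#' @param kind one of `"identity"`, `"logit"`, `"logit_increment"`,
#'   `"hypothesis_indicator"`.
#' @return An object of class `transform_spec`.
#' @examples
#' forward_transform(transform_spec("logit_increment"), 0.35, 0.20)
#' @export
transform_spec <- function(kind = c("identity", "logit", "logit_increment",
                                    "hypothesis_indicator")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("Rate transformation:", x$kind, "\n")
  invisible(x)
}

.check_unit_interior <- function(p, what) {
  # reject (not clip) probabilities at or within 1e-12 of the boundary
  if (any(!is.finite(p)) || any(p < 1e-12) || any(p > 1 - 1e-12))
    stop(what, " must lie strictly inside (0,1)")
  invisible(p)
}

#' Apply a rate transformation
#'
#' @param spec a [transform_spec].
#' @param pi response rate(s), strictly inside (0,1) for the logit kinds.
#' @param pi0 reference rate(s); required by `logit_increment` and
#'   `hypothesis_indicator`, ignored otherwise.
#' @return Transformed value(s): a real number, or 0/1 for the indicator.
#' @export
forward_transform <- function(spec, pi, pi0 = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  if (spec$kind %in% c("logit_increment", "hypothesis_indicator")) {
    if (is.null(pi0)) stop(spec$kind, " requires a reference rate pi0")
    .check_unit_interior(pi0, "pi0")
  }
  switch(spec$kind,
    identity = pi,
    logit = { .check_unit_interior(pi, "pi"); stats::qlogis(pi) },
    logit_increment = {
      .check_unit_interior(pi, "pi")
      stats::qlogis(pi) - stats::qlogis(pi0)
    },
    hypothesis_indicator = as.numeric(pi > pi0))
}

#' Invert a rate transformation
#'
#' Defined for the real-valued kinds only; the hypothesis indicator is
#' many-to-one and has no inverse (the rate is then recovered through a
#' conditional prior instead).
#'
#' @param spec a [transform_spec].
#' @param gamma transformed value(s).
#' @param pi0 reference rate(s) for `logit_increment`.
#' @return Response rate(s).
#' @export
inverse_transform <- function(spec, gamma, pi0 = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    identity = gamma,
    logit = stats::plogis(gamma),
    logit_increment = {
      if (is.null(pi0)) stop("logit_increment requires a reference rate pi0")
      .check_unit_interior(pi0, "pi0")
      stats::plogis(gamma + stats::qlogis(pi0))
    },
    hypothesis_indicator = stop(
      "the hypothesis indicator is many-to-one and cannot be inverted"))
}

# gamma-scale cutoff t such that pi > pi0  <=>  gamma > t
.gamma_cut <- function(spec, pi0) {
  switch(spec$kind,
    identity = pi0,
    logit = stats::qlogis(pi0),
    logit_increment = rep(0, length(pi0)),
    hypothesis_indicator = rep(0.5, length(pi0)))
}
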