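#' Fit the median-effect model to a dose-response curve
#'
#' Chou's median-effect equation `fa/(1-fa) = (D/Dm)^m` is linear on
#' double-log axes: `log10(fa/(1-fa)) = m*log10(D) - m*log10(Dm)`. The
#' fit is ordinary least squares of the logit-transformed fraction
#' affected on log dose; `m` is the slope (sigmoidicity), `Dm` the
#' median-effect dose recovered from the intercept, and `r` the
#' correlation coefficient of the linearized fit. Points with `fa`
#' outside `[epsilon, 1 - epsilon]` carry no information on the logit
#' scale and are dropped before fitting.
#'
#' @param dose positive dose vector, or a data.frame with columns
#'   `dose` and `fa` (e.g. from [gen_dose_response()]).
#' @param fa fractions affected in \[0, 1\] (ignored when `dose` is a
#'   data.frame).
#' @param epsilon informative-range cutoff, default 0.005.
#' @return object of class `median_effect_fit`: list with `m`, `Dm`, `r`,
#'   `n_points`, `epsilon`, `noncytotoxic` flag (`m <= 0`), and the
#'   retained points. Supports `print()`, `coef()`, `predict()`.
#' @seealso [dose_for_effect()], [combination_index()]
#' @export
fit_median_effect <- function(dose, fa = NULL, epsilon = 0.005) {
  if (is.data.frame(dose)) {
    fa <- dose$fa
    dose <- dose$dose
  }
  stopifnot(length(dose) == length(fa), epsilon > 0, epsilon < 0.5)
  if (any(dose <= 0)) stop("doses must be strictly positive", call. = FALSE)
  assert_prob(fa)
  keep <- fa >= epsilon & fa <= 1 - epsilon
  if (sum(keep) < 2) {
    stop("fewer than 2 informative points (fa within [epsilon, 1-epsilon])",
         call. = FALSE)
  }
  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  if (length(unique(x)) < 2) {
    stop("need at least 2 distinct doses among informative points",
         call. = FALSE)
  }
  ls <- stats::lm.fit(cbind(1, x), y)
  b0 <- ls$coefficients[1]; m <- ls$coefficients[2]
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  fit <- structure(list(
    m = unname(m), Dm = unname(10^(-b0 / m)), r = unname(r),
    n_points = sum(keep), epsilon = epsilon,
    noncytotoxic = unname(m <= 0),
    data = data.frame(dose = dose[keep], fa = fa[keep])
  ), class = "median_effect_fit")
  if (fit$noncytotoxic) {
    warning("non-positive slope: fit does not describe a cytotoxic response",
            call. = FALSE)
  }
  fit
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit\n")
  cat(sprintf("  m = %.4g, Dm = %.4g, r = %.4f (n = %d points)\n",
              x$m, x$Dm, x$r, x$n_points))
  if (x$noncytotoxic) cat("  flag: non-cytotoxic (m <= 0)\n")
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(m = object$m, Dm = object$Dm)
}

#' Predicted fraction affected at given doses
#'
#' @param object a `median_effect_fit`.
#' @param dose positive dose vector (defaults to the fitted doses).
#' @param ... unused.
#' @return fractions affected.
#' @export
predict.median_effect_fit <- function(object, dose = object$data$dose, ...) {
  stopifnot(all(dose > 0))
  ratio <- (dose / object$Dm)^object$m
  ratio / (1 + ratio)
}

#' Dose required for a target fraction affected
#'
#' Inverts the median-effect model: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`.
#' @param fa target fractions affected, strictly inside (0, 1).
#' @return doses in the units of the fitted curve.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) {
    stop("'fa' must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}
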