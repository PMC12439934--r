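#' Chou-Talalay combination index for a constant-ratio combination
#'
#' Fits the median-effect model to the combination curve (on total dose),
#' then evaluates, at each fraction affected of a grid, the combination
#' index `CI = d1/DxA(fa) + d2/DxB(fa)`: the doses of the two components
#' achieving `fa` in combination, each divided by the dose of that agent
#' alone producing the same effect. This is the mutually-exclusive
#' (Loewe-form) index; the non-exclusive form adds the cross-term
#' `(d1*d2)/(DxA*DxB)`. CI < 1 indicates synergy, 1 additivity, > 1
#' antagonism. A sham combination (an agent combined with itself at split
#' doses) yields CI = 1 at every `fa`.
#'
#' @param fit_a,fit_b single-agent `median_effect_fit` objects.
#' @param combo data.frame of the constant-ratio combination curve with
#'   columns `dose_a`, `dose_b` (per-point component doses) and `fa`.
#' @param fa_grid fractions affected at which CI is evaluated; must
#'   include 0.5 (the ED50 summary point). Default 0.1-0.9 by 0.1.
#' @param form `"exclusive"` (default) or `"nonexclusive"`.
#' @param epsilon informative-range cutoff for the combination fit.
#' @param band half-width of the additivity band for classification
#'   (default 0.05).
#' @return object of class `ci_result`: per-grid-point CI, `ci_at_ed50`,
#'   `ci_mean` over the grid, the classification label, the combination
#'   fit and the dose ratio. Supports `print()`.
#' @export
combination_index <- function(fit_a, fit_b, combo,
                              fa_grid = seq(0.1, 0.9, by = 0.1),
                              form = c("exclusive", "nonexclusive"),
                              epsilon = 0.005, band = 0.05) {
  form <- match.arg(form)
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"),
            all(c("dose_a", "dose_b", "fa") %in% names(combo)))
  if (!any(abs(fa_grid - 0.5) < 1e-12)) fa_grid <- sort(c(fa_grid, 0.5))
  total <- combo$dose_a + combo$dose_b
  stopifnot(all(total > 0))
  w1 <- combo$dose_a / total
  if (length(w1) > 1 && stats::sd(w1) > 1e-8 * max(1, mean(w1))) {
    stop("combination curve is not constant-ratio: component dose fractions vary",
         call. = FALSE)
  }
  w1 <- mean(w1)
  fit_c <- fit_median_effect(total, combo$fa, epsilon = epsilon)

  d_tot <- dose_for_effect(fit_c, fa_grid)
  d1 <- w1 * d_tot
  d2 <- (1 - w1) * d_tot
  dxa <- dose_for_effect(fit_a, fa_grid)
  dxb <- dose_for_effect(fit_b, fa_grid)
  ci <- d1 / dxa + d2 / dxb
  if (form == "nonexclusive") ci <- ci + (d1 * d2) / (dxa * dxb)

  ci_ed50 <- ci[abs(fa_grid - 0.5) < 1e-12]
  structure(list(
    fa_grid = fa_grid, ci = ci,
    ci_at_ed50 = ci_ed50, ci_mean = mean(ci),
    classification = classify_synergy(ci_ed50, band = band),
    form = form, ratio_a = w1, combo_fit = fit_c,
    fit_a = fit_a, fit_b = fit_b, band = band
  ), class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("Combination index (%s form, constant ratio %.3g:%.3g)\n",
              x$form, x$ratio_a, 1 - x$ratio_a))
  cat(sprintf("  CI at fa = 0.5: %.4f   mean over grid: %.4f   -> %s\n",
              x$ci_at_ed50, x$ci_mean, x$classification))
  invisible(x)
}

#' Classify a combination index value
#'
#' CI below 1 is synergistic and above 1 antagonistic; values within
#' `1 +/- band` are reported as additive (default band 0.05) so that
#' near-unity indices are not over-interpreted.
#'
#' @param ci positive combination-index value(s).
#' @param band additivity half-width, default 0.05.
#' @return character vector in {"synergistic", "additive", "antagonistic"}.
#' @export
classify_synergy <- function(ci, band = 0.05) {
  stopifnot(all(ci > 0), band >= 0)
  ifelse(abs(ci - 1) <= band + 1e-12, "additive",
         ifelse(ci < 1, "synergistic", "antagonistic"))
}
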