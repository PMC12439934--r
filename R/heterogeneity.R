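#' Discordant positivity of a sample pair
#'
#' Two samples (co-positive fractions) are discordant at threshold `tau`
#' when exactly one of them is positive, i.e. one fraction is below the
#' threshold and the other at or above it (the positive side is
#' inclusive: 0.20 vs 0.19 at tau = 0.20 is discordant).
#'
#' @param fa,fb numeric fractions in \[0, 1\] (vectorized).
#' @param tau positivity threshold, default 0.20.
#' @return integer 0/1 vector.
#' @export
pair_discordance <- function(fa, fb, tau = 0.20) {
  assert_prob(fa); assert_prob(fb)
  as.integer(xor(fa >= tau, fb >= tau))
}

#' Heterogeneity index of one unit
#'
#' Fraction of discordant unordered sample pairs within a unit (a patient
#' whose samples are its tumors, or a tumor whose samples are its cores).
#' With k positive samples out of n, the number of discordant pairs is
#' k*(n-k) and the index equals `k*(n-k) / choose(n, 2)` — identical to
#' exhaustive enumeration of all pairs.
#'
#' @param fractions numeric vector of co-positive fractions for the
#'   unit's samples.
#' @param tau positivity threshold.
#' @return index in \[0, 1\], or `NA` when the unit has fewer than two
#'   samples (non-informative; excluded from pooling).
#' @export
heterogeneity_index <- function(fractions, tau = 0.20) {
  assert_prob(fractions)
  n <- length(fractions)
  if (n < 2) return(NA_real_)
  k <- sum(fractions >= tau)
  (k * (n - k)) / (n * (n - 1) / 2)
}

#' Pooled heterogeneity index with clustered bootstrap CI
#'
#' Point estimate: mean of per-unit heterogeneity indices over informative
#' units (>= 2 samples), each unit weighted equally by default (or by its
#' number of pairs with `weighting = "pair"`). The 95% confidence interval
#' is a percentile bootstrap resampling whole units with replacement,
#' which respects the clustering of samples within patients/tumors.
#'
#' @param fractions numeric vector of co-positive fractions.
#' @param units parallel vector of unit ids (patients for the
#'   intra-patient index, tumors for the intra-tumoral index).
#' @param tau positivity threshold, default 0.20.
#' @param B bootstrap replicates (>= 200), default 2000.
#' @param seed integer seed for the bootstrap.
#' @param level label recorded in the result.
#' @param weighting `"unit"` (equal weight per unit, default) or
#'   `"pair"` (units weighted by their number of sample pairs).
#' @param conf confidence level, default 0.95.
#' @return object of class `het_boot` with the point estimate, CI bounds,
#'   per-unit indices, and bookkeeping fields.
#' @export
heterogeneity_boot <- function(fractions, units, tau = 0.20, B = 2000,
                               seed = 1L,
                               level = c("intra_patient", "intra_tumoral"),
                               weighting = c("unit", "pair"),
                               conf = 0.95) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  stopifnot(length(fractions) == length(units))
  assert_count(B, min = 200)
  by_unit <- split(fractions, units)
  idx <- vapply(by_unit, heterogeneity_index, numeric(1), tau = tau)
  n_samp <- vapply(by_unit, length, integer(1))
  inf <- !is.na(idx)
  if (!any(inf)) stop("no informative units (all have < 2 samples)", call. = FALSE)
  idx_i <- idx[inf]
  w_i <- if (weighting == "pair") choose(n_samp[inf], 2) else rep(1, sum(inf))
  est <- stats::weighted.mean(idx_i, w_i)

  boot <- with_local_seed(seed, {
    n_u <- length(idx_i)
    vapply(seq_len(B), function(b) {
      take <- sample.int(n_u, n_u, replace = TRUE)
      stats::weighted.mean(idx_i[take], w_i[take])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))

  structure(list(
    level = level, point_estimate = est, ci_low = ci[1], ci_high = ci[2],
    unit_indices = idx_i, n_units = length(idx_i),
    n_informative_pairs = sum(choose(n_samp[inf], 2)),
    n_excluded_units = sum(!inf), B = as.integer(B), seed = as.integer(seed),
    tau = tau, weighting = weighting, conf = conf
  ), class = "het_boot")
}

#' @export
print.het_boot <- function(x, ...) {
  cat(sprintf("Heterogeneity index (%s)\n", x$level))
  cat(sprintf("  estimate: %.3f  (%.0f%% bootstrap CI %.3f-%.3f, B = %d)\n",
              x$point_estimate, 100 * x$conf, x$ci_low, x$ci_high, x$B))
  cat(sprintf("  %d informative units (%d pairs), %d excluded; tau = %.2f, %s-weighted\n",
              x$n_units, x$n_informative_pairs, x$n_excluded_units,
              x$tau, x$weighting))
  invisible(x)
}

#' Heterogeneity table across marker pairs and levels
#'
#' Convenience wrapper computing the intra-patient index (tumor-level
#' co-positive fractions clustered by patient) and intra-tumoral index
#' (core-level fractions clustered by tumor) for every marker pair.
#'
#' @param tumor_summary output of [summarize_tumors()].
#' @param core_summary output of [summarize_cores()].
#' @param tau,B,seed,weighting passed to [heterogeneity_boot()]; the seed
#'   is sub-streamed per pair and level.
#' @return data.frame with level, pair, estimate, ci_low, ci_high,
#'   n_units, B, seed.
#' @export
heterogeneity_table <- function(tumor_summary, core_summary, tau = 0.20,
                                B = 2000, seed = 1L, weighting = "unit") {
  rows <- list(); k <- 0
  for (lv in c("intra_patient", "intra_tumoral")) {
    src <- if (lv == "intra_patient") tumor_summary else core_summary
    unit_col <- if (lv == "intra_patient") "patient_id" else "tumor_id"
    for (pr in MARKER_PAIRS) {
      lab <- pair_label(pr); k <- k + 1
      hb <- heterogeneity_boot(src[[paste0("copos_", lab)]], src[[unit_col]],
                               tau = tau, B = B,
                               seed = substream_seed(seed, k),
                               level = lv, weighting = weighting)
      rows[[paste(lv, lab)]] <- data.frame(
        level = lv, pair = lab, estimate = hb$point_estimate,
        ci_low = hb$ci_low, ci_high = hb$ci_high, n_units = hb$n_units,
        B = hb$B, seed = hb$seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
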