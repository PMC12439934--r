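#' Configuration for a synthetic xenograft growth study
#'
#' Exponential tumor growth on the log scale: for animal `i` in a group
#' with daily growth fraction `g`,
#' `log V = log(v0_mean) + b_i + log(1 + g) * day + e`, with per-animal
#' random intercept `b_i ~ N(0, animal_sd^2)` and lognormal measurement
#' noise `e ~ N(0, residual_sd^2)`. Defaults emulate a four-arm
#' cell-line-derived xenograft experiment: vehicle growing ~9.5%/day,
#' a Bcl-xL inhibitor arm ~6.5%, an ADC arm ~3.5% and the combination
#' ~1.5%, 7 animals per group, enrollment at ~100 mm3 and caliper
#' measurements every other day for four weeks.
#'
#' @param groups named numeric vector of daily growth fractions
#'   (each > -1).
#' @param n_animals_per_group animals per group.
#' @param days strictly increasing measurement days.
#' @param v0_mean mean enrollment volume in mm3.
#' @param animal_sd SD of the per-animal random intercept (log scale).
#' @param residual_sd residual SD (log scale).
#' @param seed integer seed.
#' @return object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(groups = c(vehicle = 0.095, A1331852 = 0.065,
                                         MGC018 = 0.035, combination = 0.015),
                              n_animals_per_group = 7,
                              days = seq(0, 28, by = 2),
                              v0_mean = 100,
                              animal_sd = 0.25,
                              residual_sd = 0.10,
                              seed = 1L) {
  stopifnot(is.numeric(groups), !is.null(names(groups)), all(groups > -1))
  assert_count(n_animals_per_group, min = 2)
  if (length(days) < 2 || any(diff(days) <= 0)) {
    stop("'days' must be strictly increasing with >= 2 timepoints",
         call. = FALSE)
  }
  stopifnot(v0_mean > 0, animal_sd >= 0, residual_sd >= 0)
  structure(list(groups = groups,
                 n_animals_per_group = as.integer(n_animals_per_group),
                 days = days, v0_mean = v0_mean, animal_sd = animal_sd,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' Generate a synthetic longitudinal tumor-volume table
#'
#' @param config a [growth_sim_config()].
#' @return list with `volumes` (animal_id, group, day, volume_mm3 in long
#'   format) and `truth` (per group: daily growth fraction and the
#'   log-scale slope `log(1 + g)`).
#' @export
gen_growth_study <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  with_local_seed(config$seed, {
    rows <- list()
    for (g in names(config$groups)) {
      slope <- log(1 + config$groups[[g]])
      for (a in seq_len(config$n_animals_per_group)) {
        b <- stats::rnorm(1, 0, config$animal_sd)
        logv <- log(config$v0_mean) + b + slope * config$days +
          stats::rnorm(length(config$days), 0, config$residual_sd)
        rows[[paste(g, a)]] <- data.frame(
          animal_id = sprintf("%s_%02d", g, a), group = g,
          day = config$days, volume_mm3 = exp(logv),
          stringsAsFactors = FALSE)
      }
    }
    volumes <- do.call(rbind, rows)
    rownames(volumes) <- NULL
    list(volumes = volumes,
         truth = data.frame(group = names(config$groups),
                            daily_growth_fraction = unname(config$groups),
                            slope = log(1 + unname(config$groups)),
                            stringsAsFactors = FALSE))
  })
}
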