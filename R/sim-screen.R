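#' Default 23-agent payload panel with mechanism-of-action annotation
#'
#' Three payload classes — DNA-damaging drugs (DDD), microtubule-disrupting
#' drugs (MDD) and innovative drugs (ID) — organized into 13 pharmacological
#' subgroups with 1-3 analogous members each. One representative per
#' subgroup (the first member) enters the pairwise-combination arm, giving
#' 13 combination agents and choose(13, 2) = 78 pairs.
#'
#' @return data.frame with columns agent, class, subgroup, combo_member.
#' @export
default_payload_panel <- function() {
  spec <- list(
    # class, subgroup, n members
    c("DDD", "topo1_inhibitor", 2), c("DDD", "topo2_inhibitor", 2),
    c("DDD", "dna_scissor", 2),     c("DDD", "dna_crosslinker", 2),
    c("DDD", "dna_alkylator", 2),
    c("MDD", "auristatin", 3), c("MDD", "maytansinoid", 2),
    c("MDD", "tubulysin", 1),  c("MDD", "eribulin_like", 1),
    c("ID", "splicing_inhibitor", 2), c("ID", "amatoxin", 1),
    c("ID", "nampt_inhibitor", 1),    c("ID", "bclxl_inhibitor", 2)
  )
  rows <- list(); k <- 0
  for (s in spec) {
    n <- as.integer(s[3])
    for (j in seq_len(n)) {
      k <- k + 1
      rows[[k]] <- data.frame(agent = sprintf("A%02d", k), class = s[1],
                              subgroup = s[2], combo_member = j == 1,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Configuration for the synthetic 384-well payload screen
#'
#' Emulates a viability screen: each agent tested at two working
#' concentrations (high and low) and the combination agents tested
#' pairwise at the low concentration, with vehicle and positive-control
#' (near-complete kill) wells on every plate. Raw luminescence is
#' `baseline * (1 - effect) * noise` with multiplicative lognormal noise,
#' the positive-valued roughly-constant-CV error structure of ATP-based
#' assays. Combination effects follow Bliss independence plus any excess
#' configured in `interaction_map`, clipped to \[0, 1\].
#'
#' @param panel payload annotation, see [default_payload_panel()].
#' @param cell_lines character vector of cell-line labels.
#' @param single_effects optional agents x cell-lines matrix of low-dose
#'   fractions affected in \[0, 1\] (dimnames required). When `NULL`,
#'   drawn uniformly in \[0.30, 0.85\] under `seed` — screens use
#'   pre-selected effective concentrations, so near-null effects are not
#'   part of the design. High-dose effect is `1 - (1 - e_low)^2`.
#' @param interaction_map optional data.frame (agent1, agent2, excess)
#'   adding Bliss excess to named combination pairs; agents must belong
#'   to the combination arm.
#' @param control_wells named counts, `c(vehicle =, positive =)`, each >= 3.
#' @param n_replicates replicate wells per condition (default 3; with the
#'   default panel this fills a 384-well plate exactly:
#'   23x2x3 + 78x3 + 12 = 384).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param baseline_rlu vehicle-level luminescence.
#' @param positive_effect fraction affected in positive-control wells
#'   (just below 1 so luminescence stays positive).
#' @param seed integer seed.
#' @return object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(panel = default_payload_panel(),
                              cell_lines = c("C4-2B", "22Rv1", "LuCaP176",
                                             "MSKCC_EF1"),
                              single_effects = NULL,
                              interaction_map = NULL,
                              control_wells = c(vehicle = 6, positive = 6),
                              n_replicates = 3,
                              noise_cv = 0.05,
                              baseline_rlu = 1e6,
                              positive_effect = 0.999,
                              seed = 1L) {
  stopifnot(all(c("agent", "class", "subgroup", "combo_member") %in% names(panel)))
  assert_count(n_replicates)
  stopifnot(all(control_wells >= 3), noise_cv >= 0, baseline_rlu > 0)
  assert_prob(positive_effect)
  combo_agents <- panel$agent[panel$combo_member]
  if (!is.null(single_effects)) {
    stopifnot(is.matrix(single_effects),
              setequal(rownames(single_effects), panel$agent),
              setequal(colnames(single_effects), cell_lines))
    assert_prob(single_effects)
    single_effects <- single_effects[panel$agent, cell_lines, drop = FALSE]
  }
  if (!is.null(interaction_map)) {
    stopifnot(all(c("agent1", "agent2", "excess") %in% names(interaction_map)))
    bad <- setdiff(unique(c(interaction_map$agent1, interaction_map$agent2)),
                   combo_agents)
    if (length(bad)) {
      stop("interaction_map names agents outside the combination arm: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(panel = panel, cell_lines = cell_lines,
                 combo_agents = combo_agents,
                 single_effects = single_effects,
                 interaction_map = interaction_map,
                 control_wells = control_wells,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, baseline_rlu = baseline_rlu,
                 positive_effect = positive_effect,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

# lognormal multiplicative noise with unit mean and given CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic screen plates with ground truth
#'
#' One 384-well-style plate per cell line: single agents at high and low
#' dose, all pairwise combinations of the combination arm at low dose,
#' and vehicle/positive control wells, each with `n_replicates` wells.
#'
#' @param config a [screen_sim_config()].
#' @return list with `plates` (named list of per-line data.frames: well,
#'   row, col, agent1, agent2, dose_level, control, rlu; cell line in
#'   attribute `cell_line`) and `truth` (list with the low/high single-
#'   effect matrices and the per-line combination-effect tables).
#' @export
gen_screen_plate <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  agents <- config$panel$agent
  combo <- config$combo_agents
  pairs <- utils::combn(combo, 2)

  with_local_seed(config$seed, {
    e_low <- config$single_effects
    if (is.null(e_low)) {
      e_low <- matrix(stats::runif(length(agents) * length(config$cell_lines),
                                   0.30, 0.85),
                      nrow = length(agents),
                      dimnames = list(agents, config$cell_lines))
    }
    e_high <- 1 - (1 - e_low)^2

    excess_of <- function(a1, a2) {
      im <- config$interaction_map
      if (is.null(im)) return(0)
      hit <- (im$agent1 == a1 & im$agent2 == a2) |
             (im$agent1 == a2 & im$agent2 == a1)
      if (any(hit)) sum(im$excess[hit]) else 0
    }

    plates <- list(); combo_truth <- list()
    for (line in config$cell_lines) {
      cond <- rbind(
        data.frame(agent1 = rep(agents, 2), agent2 = NA_character_,
                   dose_level = rep(c("high", "low"), each = length(agents)),
                   control = "none",
                   effect = c(e_high[, line], e_low[, line]),
                   stringsAsFactors = FALSE),
        data.frame(agent1 = pairs[1, ], agent2 = pairs[2, ],
                   dose_level = "low", control = "none",
                   effect = pmin(1, mapply(function(a, b) {
                     bliss_expected(e_low[a, line], e_low[b, line]) +
                       excess_of(a, b)
                   }, pairs[1, ], pairs[2, ])),
                   stringsAsFactors = FALSE),
        data.frame(agent1 = NA_character_, agent2 = NA_character_,
                   dose_level = NA_character_,
                   control = rep(c("vehicle", "positive"),
                                 config$control_wells[c("vehicle", "positive")]),
                   effect = rep(c(0, config$positive_effect),
                                config$control_wells[c("vehicle", "positive")]),
                   stringsAsFactors = FALSE))
      # replicate condition wells (controls already listed per well)
      is_ctrl <- cond$control != "none"
      cond <- rbind(cond[rep(which(!is_ctrl), each = config$n_replicates), ],
                    cond[is_ctrl, ])
      n <- nrow(cond)
      row_i <- ((seq_len(n) - 1) %/% 24) + 1
      col_i <- ((seq_len(n) - 1) %% 24) + 1
      plate <- data.frame(
        well = sprintf("%s%02d", LETTERS[row_i], col_i),
        row = LETTERS[row_i], col = col_i,
        agent1 = cond$agent1, agent2 = cond$agent2,
        dose_level = cond$dose_level, control = cond$control,
        rlu = config$baseline_rlu * (1 - cond$effect) *
          .ln_noise(n, config$noise_cv),
        stringsAsFactors = FALSE)
      rownames(plate) <- NULL
      attr(plate, "cell_line") <- line
      plates[[line]] <- plate

      combo_truth[[line]] <- data.frame(
        cell_line = line, agent1 = pairs[1, ], agent2 = pairs[2, ],
        e1 = e_low[pairs[1, ], line], e2 = e_low[pairs[2, ], line],
        excess = mapply(excess_of, pairs[1, ], pairs[2, ]),
        e_combo = pmin(1, bliss_expected(e_low[pairs[1, ], line],
                                         e_low[pairs[2, ], line]) +
                         mapply(excess_of, pairs[1, ], pairs[2, ])),
        stringsAsFactors = FALSE)
    }
    combos <- do.call(rbind, combo_truth)
    rownames(combos) <- NULL
    list(plates = plates,
         truth = list(e_low = e_low, e_high = e_high, combos = combos))
  })
}

#' Generate a median-effect dose-response curve
#'
#' Fraction affected follows the median-effect (Hill) model
#' `fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)`; noise is multiplicative lognormal
#' on the viability `1 - fa`, then clipped back to \[0, 1\].
#'
#' @param m sigmoidicity (slope) > 0.
#' @param Dm median-effect dose > 0 (same units as `doses`).
#' @param doses positive dose vector.
#' @param noise_cv coefficient of variation of the viability noise.
#' @param n_replicates replicates per dose.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return data.frame with dose, replicate, fa.
#' @export
gen_dose_response <- function(m, Dm, doses, noise_cv = 0, n_replicates = 1,
                              seed = NULL) {
  stopifnot(m > 0, Dm > 0)
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  assert_count(n_replicates)
  d <- rep(doses, each = n_replicates)
  fa0 <- (d / Dm)^m / (1 + (d / Dm)^m)
  with_local_seed(seed, {
    v <- pmin(1, pmax(0, (1 - fa0) * .ln_noise(length(d), noise_cv)))
    data.frame(dose = d, replicate = rep(seq_len(n_replicates), length(doses)),
               fa = 1 - v)
  })
}
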