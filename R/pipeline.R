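#' Default end-to-end run configuration
#'
#' One namespace for every tunable of the pipeline. Thresholds:
#' `tau = 0.20` (double-positive tumor threshold, from the 20%-of-cells
#' co-staining rule), `delta = 0.10` (Bliss-excess nomination margin, a
#' configuration choice), `ci_cutoff = 1.0` (combination-index synergy
#' boundary), `epsilon = 0.005` (median-effect informative range),
#' `B = 2000` (bootstrap replicates). Inputs default to the synthetic
#' generators; replace any `sim` entry with a `path` entry naming a CSV
#' to run on real tables.
#'
#' @param seed master seed; every stage derives a sub-stream from it.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    tau = 0.20, delta = 0.10, ci_cutoff = 1.0, epsilon = 0.005, B = 2000L,
    min_lines = 2L,
    mif = list(sim = mif_sim_config(seed = substream_seed(seed, 1))),
    screen = list(sim = screen_sim_config(
      seed = substream_seed(seed, 2),
      interaction_map = data.frame(agent1 = "A01", agent2 = "A22",
                                   excess = 0.25))),
    dose_response = list(
      # validation arm: single agents and a 1:1 fixed-ratio combination
      agents = list(A = list(m = 1.5, Dm = 2), B = list(m = 2.5, Dm = 10)),
      doses = c(0.5, 1, 2, 4, 8, 16),
      noise_cv = 0.05, n_replicates = 3,
      combo_synergy_fold = 2  # combo Dm is this fold lower than additivity
    ),
    growth = list(sim = growth_sim_config(seed = substream_seed(seed, 4)))
  )
}

#' Validate pipeline input tables
#'
#' Schema, range and referential-integrity checks with row-level
#' diagnostics. Returns a report rather than stopping: each failure is
#' one row (table, check, row index, message); zero rows means all
#' supplied tables are well formed.
#'
#' @param cells optional single-cell mIF table.
#' @param plates optional named list of plate tables.
#' @param dose_response optional dose-response table (dose, fa).
#' @param volumes optional longitudinal tumor-volume table.
#' @return data.frame validation report.
#' @export
validate_inputs <- function(cells = NULL, plates = NULL,
                            dose_response = NULL, volumes = NULL) {
  fails <- list()
  add <- function(table, check, row, message) {
    fails[[length(fails) + 1]] <<- data.frame(
      table = table, check = check, row = row, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.null(cells)) {
    need <- c("cell_id", "core_id", "tumor_id", "patient_id", "phenotype",
              paste0(MARKERS, "_class"))
    for (col in setdiff(need, names(cells))) {
      add("cells", "schema", NA_integer_, paste("missing column", col))
    }
    if (all(need %in% names(cells))) {
      for (mk in MARKERS) {
        cls <- cells[[paste0(mk, "_class")]]
        bad <- which(!(cls %in% 0:3))
        for (r in bad) add("cells", "range", r,
                           paste0(mk, "_class outside {0,1,2,3}"))
      }
      # a core must sit inside one tumor, a tumor inside one patient
      core_tum <- tapply(cells$tumor_id, cells$core_id,
                         function(x) length(unique(x)))
      for (cid in names(core_tum)[core_tum > 1]) {
        add("cells", "referential", NA_integer_,
            paste("core", cid, "maps to multiple tumors"))
      }
      tum_pat <- tapply(cells$patient_id, cells$tumor_id,
                        function(x) length(unique(x)))
      for (tid in names(tum_pat)[tum_pat > 1]) {
        add("cells", "referential", NA_integer_,
            paste("tumor", tid, "maps to multiple patients"))
      }
    }
  }
  if (!is.null(plates)) {
    for (nm in names(plates)) {
      pl <- plates[[nm]]
      need <- c("agent1", "agent2", "dose_level", "control", "rlu")
      for (col in setdiff(need, names(pl))) {
        add(paste0("plate_", nm), "schema", NA_integer_,
            paste("missing column", col))
      }
      if (all(need %in% names(pl))) {
        for (r in which(pl$rlu < 0)) {
          add(paste0("plate_", nm), "range", r, "negative rlu")
        }
        if (sum(pl$control == "vehicle") < 3) {
          add(paste0("plate_", nm), "schema", NA_integer_,
              "fewer than 3 vehicle wells")
        }
        if (sum(pl$control == "positive") < 3) {
          add(paste0("plate_", nm), "schema", NA_integer_,
              "fewer than 3 positive-control wells")
        }
        orphan <- which(pl$control == "none" & is.na(pl$agent1))
        for (r in orphan) {
          add(paste0("plate_", nm), "referential", r,
              "treated well without agent annotation")
        }
      }
    }
  }
  if (!is.null(dose_response)) {
    for (col in setdiff(c("dose", "fa"), names(dose_response))) {
      add("dose_response", "schema", NA_integer_, paste("missing column", col))
    }
    if (all(c("dose", "fa") %in% names(dose_response))) {
      for (r in which(dose_response$dose <= 0)) {
        add("dose_response", "range", r, "non-positive dose")
      }
      for (r in which(dose_response$fa < 0 | dose_response$fa > 1)) {
        add("dose_response", "range", r, "fa outside [0, 1]")
      }
    }
  }
  if (!is.null(volumes)) {
    need <- c("animal_id", "group", "day", "volume_mm3")
    for (col in setdiff(need, names(volumes))) {
      add("volumes", "schema", NA_integer_, paste("missing column", col))
    }
    if (all(need %in% names(volumes))) {
      for (r in which(volumes$volume_mm3 <= 0)) {
        add("volumes", "range", r, "non-positive volume")
      }
      multi <- tapply(volumes$group, volumes$animal_id,
                      function(x) length(unique(x)))
      for (aid in names(multi)[multi > 1]) {
        add("volumes", "referential", NA_integer_,
            paste("animal", aid, "assigned to multiple groups"))
      }
    }
  }
  if (length(fails) == 0) {
    return(data.frame(table = character(), check = character(),
                      row = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, fails)
  rownames(out) <- NULL
  out
}

.write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from one configuration
#'
#' Orchestrates synthesize -> validate -> quantify -> heterogeneity ->
#' screen/synergy -> dose-response/CI -> growth, writing every stage
#' output as CSV into `out_dir` together with a machine-readable
#' `manifest.json` (configuration hash, seed, package version, file
#' checksums). A rerun with the same configuration reproduces
#' byte-identical stage outputs for synthetic inputs.
#'
#' @param config configuration list from [default_run_config()] (or a
#'   path to a YAML file with overrides of the scalar settings).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         quiet = FALSE) {
  if (is.character(config)) {
    over <- yaml::read_yaml(config)
    config <- default_run_config(seed = over$seed %||% 1L)
    for (nm in intersect(names(over),
                         c("tau", "delta", "ci_cutoff", "epsilon", "B",
                           "min_lines"))) {
      config[[nm]] <- over[[nm]]
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[adcsynergy] ", sprintf(...))
  files <- character()
  res <- list(config = config)

  # --- stage: inputs -----------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  say("stage simulate (seed %d)", config$seed)
  mif <- stage("simulate.mif", {
    if (!is.null(config$mif$path)) {
      list(cells = utils::read.csv(config$mif$path), truth = NULL)
    } else gen_mif_dataset(config$mif$sim)
  })
  screen <- stage("simulate.screen", {
    if (is.null(config$screen$sim)) NULL else gen_screen_plate(config$screen$sim)
  })
  growth_in <- stage("simulate.growth", {
    if (!is.null(config$growth$path)) {
      list(volumes = utils::read.csv(config$growth$path), truth = NULL)
    } else if (is.null(config$growth$sim)) {
      stop("growth stage enabled but neither 'path' nor 'sim' configured")
    } else gen_growth_study(config$growth$sim)
  })

  report <- validate_inputs(cells = mif$cells,
                            plates = if (!is.null(screen)) screen$plates,
                            volumes = growth_in$volumes)
  files["validation"] <- .write_stage_csv(report, out_dir, "validation.csv")
  if (nrow(report) > 0) {
    stop("input validation failed; see validation.csv (",
         nrow(report), " failures)", call. = FALSE)
  }
  files["cells"] <- .write_stage_csv(mif$cells, out_dir, "cells.csv")
  if (!is.null(mif$truth)) {
    files["truth_mif"] <- .write_stage_csv(mif$truth, out_dir, "truth_mif.csv")
  }

  # --- stage: mIF quantification ----------------------------------------
  say("stage mifquant")
  core_sum <- stage("mifquant", summarize_cores(mif$cells))
  tumor_sum <- stage("mifquant",
                     classify_double_positive(summarize_tumors(core_sum),
                                              tau = config$tau))
  roll <- stage("mifquant", patient_rollup(tumor_sum, tau = config$tau))
  ph_tests <- stage("mifquant", {
    do.call(rbind, lapply(MARKERS, function(mk) {
      tb <- compare_phenotypes(tumor_sum[[paste0("h_", mk)]],
                               tumor_sum$phenotype)
      cbind(marker = mk, tb, stringsAsFactors = FALSE)
    }))
  })
  files["core_summary"] <- .write_stage_csv(core_sum, out_dir, "core_summary.csv")
  files["tumor_summary"] <- .write_stage_csv(tumor_sum, out_dir, "tumor_summary.csv")
  files["patient_summary"] <- .write_stage_csv(roll$patients, out_dir,
                                               "patient_summary.csv")
  files["cohort_rollup"] <- .write_stage_csv(roll$cohort, out_dir,
                                             "cohort_rollup.csv")
  files["phenotype_tests"] <- .write_stage_csv(ph_tests, out_dir,
                                               "phenotype_tests.csv")
  res$tumor_summary <- tumor_sum
  res$rollup <- roll

  # --- stage: heterogeneity ---------------------------------------------
  say("stage heterogeneity (B = %d)", config$B)
  het <- stage("heterogeneity",
               heterogeneity_table(tumor_sum, core_sum, tau = config$tau,
                                   B = config$B,
                                   seed = substream_seed(config$seed, 3)))
  files["heterogeneity"] <- .write_stage_csv(het, out_dir, "heterogeneity.csv")
  res$heterogeneity <- het

  # --- stage: screen normalization + nomination -------------------------
  if (!is.null(screen)) {
    say("stage synergy screen")
    effects <- stage("synergy.normalize", {
      do.call(rbind, lapply(screen$plates, normalize_plate))
    })
    rownames(effects) <- NULL
    noms <- stage("synergy.nominate",
                  nominate_pairs(effects, config$screen$sim$panel,
                                 delta = config$delta,
                                 min_lines = config$min_lines))
    for (nm in names(screen$plates)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", nm)
      files[paste0("plate_", safe)] <-
        .write_stage_csv(screen$plates[[nm]], out_dir,
                         paste0("plate_", safe, ".csv"))
    }
    files["effects"] <- .write_stage_csv(effects, out_dir, "effects.csv")
    files["nominations"] <- .write_stage_csv(noms, out_dir, "nominations.csv")
    res$effects <- effects
    res$nominations <- noms
  }

  # --- stage: dose-response validation + combination index --------------
  if (!is.null(config$dose_response)) {
    say("stage combination index")
    dr <- config$dose_response
    ci_seed <- substream_seed(config$seed, 5)
    ci_out <- stage("synergy.ci", {
      cvA <- gen_dose_response(dr$agents$A$m, dr$agents$A$Dm, dr$doses,
                               noise_cv = dr$noise_cv,
                               n_replicates = dr$n_replicates,
                               seed = substream_seed(ci_seed, 1))
      cvB <- gen_dose_response(dr$agents$B$m, dr$agents$B$Dm,
                               dr$doses * dr$agents$B$Dm / dr$agents$A$Dm,
                               noise_cv = dr$noise_cv,
                               n_replicates = dr$n_replicates,
                               seed = substream_seed(ci_seed, 2))
      fitA <- fit_median_effect(cvA, epsilon = config$epsilon)
      fitB <- fit_median_effect(cvB, epsilon = config$epsilon)
      # equipotent combination (doses mixed in proportion to the Dm's);
      # at fa = 0.5 the Loewe-additive total dose is then
      # 1 / (wA/DmA + wB/DmB); synergy is implanted as a fold-drop of
      # the combination Dm below that additive reference
      m_c <- (dr$agents$A$m + dr$agents$B$m) / 2
      wA <- dr$agents$A$Dm / (dr$agents$A$Dm + dr$agents$B$Dm)
      Dm_add <- 1 / (wA / dr$agents$A$Dm + (1 - wA) / dr$agents$B$Dm)
      Dm_c <- Dm_add / dr$combo_synergy_fold
      combo_raw <- gen_dose_response(m_c, Dm_c,
                                     dr$doses * Dm_c / dr$agents$A$Dm,
                                     noise_cv = dr$noise_cv,
                                     n_replicates = dr$n_replicates,
                                     seed = substream_seed(ci_seed, 3))
      combo <- data.frame(dose_a = wA * combo_raw$dose,
                          dose_b = (1 - wA) * combo_raw$dose,
                          fa = combo_raw$fa)
      ci <- combination_index(fitA, fitB, combo, epsilon = config$epsilon)
      fits <- data.frame(
        curve = c("A", "B", "combo"),
        m = c(fitA$m, fitB$m, ci$combo_fit$m),
        Dm = c(fitA$Dm, fitB$Dm, ci$combo_fit$Dm),
        r = c(fitA$r, fitB$r, ci$combo_fit$r),
        n_points = c(fitA$n_points, fitB$n_points, ci$combo_fit$n_points),
        stringsAsFactors = FALSE)
      list(fits = fits,
           ci = data.frame(fa = ci$fa_grid, ci = ci$ci,
                           ci_at_ed50 = ci$ci_at_ed50, ci_mean = ci$ci_mean,
                           classification = ci$classification,
                           stringsAsFactors = FALSE),
           ci_obj = ci,
           curves = rbind(cbind(curve = "A", cvA), cbind(curve = "B", cvB),
                          cbind(curve = "combo", combo_raw)))
    })
    files["dose_response"] <- .write_stage_csv(ci_out$curves, out_dir,
                                               "dose_response.csv")
    files["medianeffect_fits"] <- .write_stage_csv(ci_out$fits, out_dir,
                                                   "medianeffect_fits.csv")
    files["ci_results"] <- .write_stage_csv(ci_out$ci, out_dir, "ci_results.csv")
    res$ci <- ci_out$ci_obj
  }

  # --- stage: growth model ----------------------------------------------
  say("stage growth")
  gfit <- stage("growth", fit_growth(growth_in$volumes))
  grep_ <- stage("growth", growth_report(gfit))
  files["volumes"] <- .write_stage_csv(growth_in$volumes, out_dir, "volumes.csv")
  files["growth_fit"] <- .write_stage_csv(gfit$slopes, out_dir, "growth_fit.csv")
  files["growth_contrasts"] <- .write_stage_csv(gfit$contrasts, out_dir,
                                                "growth_contrasts.csv")
  files["growth_report"] <- .write_stage_csv(grep_, out_dir, "growth_report.csv")
  res$growth <- gfit

  # --- manifest ----------------------------------------------------------
  scal <- config[c("seed", "tau", "delta", "ci_cutoff", "epsilon", "B",
                   "min_lines")]
  manifest <- list(
    package = "adcsynergy",
    version = as.character(utils::packageVersion("adcsynergy")),
    seed = config$seed,
    config = scal,
    config_hash = substr(.hash_obj(config), 1, 16),
    files = as.list(unname(vapply(files, function(f) {
      unname(tools::md5sum(f))
    }, character(1)))))
  names(manifest$files) <- basename(unlist(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  say("done: %d files in %s", length(files) + 1, out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable md5 of an R object via its serialized representation
.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
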