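#' Default per-phenotype marker intensity-class model
#'
#' Probabilities of the four staining classes (negative, weak, moderate,
#' strong) for each marker within each mCRPC phenotype. The AR-active
#' phenotype expresses all three surface antigens broadly; the
#' neuroendocrine phenotype largely loses PSMA, consistent with the
#' AR-regulated biology of the three targets. Class frequencies are free
#' parameters of the simulation, not calibrated estimates.
#'
#' @return named list: phenotype -> marker -> numeric(4) class probabilities.
#' @export
default_marker_model <- function() {
  list(
    "AR+/NE-" = list(
      b7h3   = c(0.45, 0.21, 0.19, 0.15),
      psma   = c(0.47, 0.20, 0.19, 0.14),
      steap1 = c(0.48, 0.20, 0.18, 0.14)),
    "AR+/NE+" = list(
      b7h3   = c(0.45, 0.25, 0.20, 0.10),
      psma   = c(0.50, 0.25, 0.15, 0.10),
      steap1 = c(0.45, 0.25, 0.20, 0.10)),
    "AR-/NE-" = list(
      b7h3   = c(0.60, 0.20, 0.12, 0.08),
      psma   = c(0.70, 0.15, 0.10, 0.05),
      steap1 = c(0.60, 0.20, 0.12, 0.08)),
    "AR-/NE+" = list(
      b7h3   = c(0.55, 0.20, 0.15, 0.10),
      psma   = c(0.80, 0.10, 0.06, 0.04),
      steap1 = c(0.70, 0.15, 0.10, 0.05))
  )
}

#' Configuration for the synthetic multiplexed-IF cohort
#'
#' Describes a tissue-microarray-like cohort: patients contribute one or
#' more metastatic tumors, each tumor is sampled as `cores_per_tumor`
#' cores, and each core contains segmented cells carrying an ordinal
#' staining class (0 = negative, 1 = weak, 2 = moderate, 3 = strong) for
#' each of B7-H3, PSMA and STEAP1. Within a cell, marker classes are
#' coupled through an equicorrelated Gaussian copula so that joint
#' positivity of marker pairs can be tuned from near-independence to
#' comonotonicity.
#'
#' @param n_patients number of patients (default 58, the cohort size the
#'   generator emulates).
#' @param tumors_per_patient single count, or length-2 range sampled
#'   uniformly per patient (default 2-4, giving ~3 tumors/patient).
#' @param cores_per_tumor cores sampled per tumor (default 3, triplicate).
#' @param cells_per_core segmented cells per core.
#' @param phenotype_mix named probabilities over the four phenotypes;
#'   phenotype is assigned per tumor.
#' @param marker_model per-phenotype per-marker class probabilities; see
#'   [default_marker_model()].
#' @param copositivity_coupling latent copula correlation shared by all
#'   marker pairs; must lie in (-0.5, 1] (three equicorrelated markers
#'   admit no correlation below -1/2). 0 = independent markers,
#'   1 = comonotone (co-positive fraction attains min of the marginals).
#' @param tumor_sd SD of the per-tumor per-marker shift of the latent
#'   staining scale (probit scale). Makes expression vary from tumor to
#'   tumor within a phenotype, as metastatic sites do; drives
#'   intra-patient heterogeneity. Set 0 for identical tumors.
#' @param core_sd SD of the per-core per-marker latent shift within a
#'   tumor; drives intra-tumoral heterogeneity.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `mif_sim_config`.
#' @export
mif_sim_config <- function(n_patients = 58,
                           tumors_per_patient = c(2L, 4L),
                           cores_per_tumor = 3,
                           cells_per_core = 200,
                           phenotype_mix = c("AR+/NE-" = 0.83, "AR+/NE+" = 0.06,
                                             "AR-/NE-" = 0.05, "AR-/NE+" = 0.06),
                           marker_model = default_marker_model(),
                           copositivity_coupling = 0.35,
                           tumor_sd = 0.5,
                           core_sd = 0.2,
                           seed = 1L) {
  assert_count(n_patients)
  assert_count(cores_per_tumor)
  assert_count(cells_per_core)
  if (!length(tumors_per_patient) %in% c(1, 2) || any(tumors_per_patient < 1)) {
    stop("'tumors_per_patient' must be a count or a length-2 range >= 1",
         call. = FALSE)
  }
  if (!setequal(names(phenotype_mix), PHENOTYPES)) {
    stop("'phenotype_mix' must be named with the four phenotypes", call. = FALSE)
  }
  assert_prob(phenotype_mix)
  if (abs(sum(phenotype_mix) - 1) > 1e-8) {
    stop("'phenotype_mix' must sum to 1", call. = FALSE)
  }
  for (ph in PHENOTYPES) {
    mm <- marker_model[[ph]]
    if (is.null(mm)) stop("marker_model missing phenotype ", ph, call. = FALSE)
    for (mk in MARKERS) {
      p <- mm[[mk]]
      if (is.null(p) || length(p) != 4) {
        stop("marker_model[['", ph, "']][['", mk, "']] must have 4 class ",
             "probabilities", call. = FALSE)
      }
      assert_prob(p, paste0("marker_model$`", ph, "`$", mk))
      if (abs(sum(p) - 1) > 1e-8) {
        stop("class probabilities for ", ph, "/", mk, " must sum to 1",
             call. = FALSE)
      }
    }
  }
  if (!is.numeric(copositivity_coupling) || length(copositivity_coupling) != 1 ||
      copositivity_coupling <= -0.5 || copositivity_coupling > 1) {
    stop("'copositivity_coupling' must lie in (-0.5, 1]", call. = FALSE)
  }
  stopifnot(tumor_sd >= 0, core_sd >= 0)
  structure(list(
    n_patients = as.integer(n_patients),
    tumors_per_patient = as.integer(tumors_per_patient),
    cores_per_tumor = as.integer(cores_per_tumor),
    cells_per_core = as.integer(cells_per_core),
    phenotype_mix = phenotype_mix[PHENOTYPES],
    marker_model = marker_model,
    copositivity_coupling = copositivity_coupling,
    tumor_sd = tumor_sd, core_sd = core_sd,
    seed = as.integer(seed)
  ), class = "mif_sim_config")
}

# Latent equicorrelated standard normals, n x k. rho >= 0 via the
# one-factor representation (valid up to rho = 1 exactly); negative rho
# via Cholesky of the equicorrelation matrix.
.equicorr_normals <- function(n, k, rho) {
  if (rho >= 0) {
    w <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * k), n, k)
    sqrt(rho) * w + sqrt(1 - rho) * e
  } else {
    R <- matrix(rho, k, k); diag(R) <- 1
    matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  }
}

# Exact generating (co-)positivity fractions for one core under the
# copula: a cell is positive for marker j iff its latent normal (shifted
# by the tumor- and core-level effects) exceeds qnorm(P(class = negative)),
# i.e. iff the equicorrelated residual exceeds thr_j - shift_j.
.core_truth <- function(marker_probs, rho, shift = c(0, 0, 0)) {
  thr <- vapply(MARKERS, function(mk) stats::qnorm(marker_probs[[mk]][1]),
                numeric(1)) - shift
  pos <- stats::pnorm(thr, lower.tail = FALSE)
  copos <- vapply(MARKER_PAIRS, function(pr) {
    bvn_upper(thr[pr[1]], thr[pr[2]], rho)
  }, numeric(1))
  names(copos) <- vapply(MARKER_PAIRS, pair_label, character(1))
  triple <- mvn_upper_equicorr(unname(thr), rho)
  list(pos = pos, copos = copos, triple = triple)
}

#' Generate a synthetic multiplexed-IF cell table with ground truth
#'
#' Simulates the full cohort described by a [mif_sim_config()]: per-cell
#' ordinal staining classes for B7-H3, PSMA and STEAP1 with copula-coupled
#' co-positivity, organized as patients > tumors > cores > cells. The
#' companion truth table carries the exact generating (co-)positivity
#' fractions per tumor, for parameter-recovery tests of the downstream
#' quantification cascade.
#'
#' @param config a [mif_sim_config()].
#' @return list with elements `cells` (one row per cell: cell_id, core_id,
#'   tumor_id, patient_id, phenotype, b7h3_class, psma_class, steap1_class)
#'   and `truth` (one row per tumor with generating fractions: pos_*,
#'   copos_*, triple_pos).
#' @export
gen_mif_dataset <- function(config) {
  stopifnot(inherits(config, "mif_sim_config"))
  rho <- config$copositivity_coupling
  nmk <- length(MARKERS)

  with_local_seed(config$seed, {
    tpp <- config$tumors_per_patient
    n_tum_per_pat <- if (length(tpp) == 1) {
      rep(tpp, config$n_patients)
    } else {
      sample(seq(tpp[1], tpp[2]), config$n_patients, replace = TRUE)
    }
    n_tumors <- sum(n_tum_per_pat)
    tum_patient <- rep(sprintf("P%03d", seq_len(config$n_patients)), n_tum_per_pat)
    tum_id <- sprintf("%s_T%d", tum_patient,
                      unlist(lapply(n_tum_per_pat, seq_len)))
    tum_phenotype <- sample(PHENOTYPES, n_tumors, replace = TRUE,
                            prob = config$phenotype_mix)

    cells <- vector("list", n_tumors)
    truth_rows <- vector("list", n_tumors)
    for (i in seq_len(n_tumors)) {
      mm <- config$marker_model[[tum_phenotype[i]]]
      cuts <- lapply(MARKERS, function(mk) stats::qnorm(cumsum(mm[[mk]])[1:3]))
      d_tumor <- stats::rnorm(nmk, 0, config$tumor_sd)
      core_list <- vector("list", config$cores_per_tumor)
      core_truth <- matrix(0, config$cores_per_tumor, 2 * nmk + 1)
      for (co in seq_len(config$cores_per_tumor)) {
        d_core <- d_tumor + stats::rnorm(nmk, 0, config$core_sd)
        z <- sweep(.equicorr_normals(config$cells_per_core, nmk, rho), 2,
                   d_core, "+")
        cls <- sapply(seq_len(nmk), function(j) findInterval(z[, j], cuts[[j]]))
        core_list[[co]] <- cls
        tr <- .core_truth(mm, rho, shift = d_core)
        core_truth[co, ] <- c(tr$pos, tr$copos, tr$triple)
      }
      cls <- do.call(rbind, core_list)
      core <- rep(seq_len(config$cores_per_tumor), each = config$cells_per_core)
      cells[[i]] <- data.frame(
        cell_id = sprintf("%s_C%d_c%04d", tum_id[i], core,
                          sequence(rep(config$cells_per_core,
                                       config$cores_per_tumor))),
        core_id = sprintf("%s_C%d", tum_id[i], core),
        tumor_id = tum_id[i],
        patient_id = tum_patient[i],
        phenotype = tum_phenotype[i],
        b7h3_class = cls[, 1], psma_class = cls[, 2], steap1_class = cls[, 3],
        stringsAsFactors = FALSE)
      # tumor-level truth: mean of the exact per-core generating fractions
      truth_rows[[i]] <- colMeans(core_truth)
    }
    cells <- do.call(rbind, cells)
    rownames(cells) <- NULL

    truth <- data.frame(
      tumor_id = tum_id, patient_id = tum_patient, phenotype = tum_phenotype,
      stringsAsFactors = FALSE)
    tm <- do.call(rbind, truth_rows)
    colnames(tm) <- c(paste0("pos_", MARKERS),
                      paste0("copos_", vapply(MARKER_PAIRS, pair_label,
                                              character(1))),
                      "triple_pos")
    truth <- cbind(truth, as.data.frame(tm))
    rownames(truth) <- NULL
    list(cells = cells, truth = truth)
  })
}
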