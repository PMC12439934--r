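#' H-score of a marker over a set of cells
#'
#' Immunostaining summary combining frequency and intensity: each cell's
#' ordinal class (0 = negative, 1 = weak, 2 = moderate, 3 = strong) is
#' weighted by the percentage of cells in that class,
#' `h = 1*pct_weak + 2*pct_moderate + 3*pct_strong`, with percentages on
#' the 0-100 scale, so the score ranges 0-300.
#'
#' @param cells data.frame of cell records (see [gen_mif_dataset()] schema).
#' @param marker one of `"b7h3"`, `"psma"`, `"steap1"`.
#' @return numeric H-score in \[0, 300\].
#' @export
h_score <- function(cells, marker) {
  assert_cells(cells)
  cls <- cells[[marker_class_col(marker)]]
  100 * mean(cls == 1) + 200 * mean(cls == 2) + 300 * mean(cls == 3)
}

#' Fraction of cells positive for a marker
#'
#' A cell is positive when it stains at least weakly (class >= 1); the
#' weak, moderate and strong classes are pooled.
#'
#' @inheritParams h_score
#' @return fraction in \[0, 1\].
#' @export
positive_fraction <- function(cells, marker) {
  assert_cells(cells)
  mean(cells[[marker_class_col(marker)]] >= 1)
}

#' Fraction of cells co-positive for two (or three) markers
#'
#' Fraction of cells positive (class >= 1) for every marker listed.
#'
#' @inheritParams h_score
#' @param markers character vector of 2 or 3 marker names.
#' @return fraction in \[0, 1\].
#' @export
copositive_fraction <- function(cells, markers) {
  assert_cells(cells)
  stopifnot(length(markers) >= 2)
  pos <- rep(TRUE, nrow(cells))
  for (mk in markers) pos <- pos & cells[[marker_class_col(mk)]] >= 1
  mean(pos)
}

#' Fraction of cells negative for both markers of a pair
#'
#' @inheritParams copositive_fraction
#' @return fraction in \[0, 1\].
#' @export
conegative_fraction <- function(cells, markers) {
  assert_cells(cells)
  stopifnot(length(markers) == 2)
  neg <- rep(TRUE, nrow(cells))
  for (mk in markers) neg <- neg & cells[[marker_class_col(mk)]] == 0
  mean(neg)
}

#' Per-core summaries of H-scores and (co-)positivity
#'
#' Collapses the single-cell table to one row per core: per-marker H-score
#' and positive fraction, per-pair co-positive and co-negative fractions,
#' the triple-positive fraction, and the cell count.
#'
#' @inheritParams h_score
#' @return data.frame, one row per core, carrying core/tumor/patient ids
#'   and phenotype.
#' @export
summarize_cores <- function(cells) {
  assert_cells(cells)
  idx <- split(seq_len(nrow(cells)), cells$core_id)
  rows <- lapply(idx, function(i) {
    cc <- cells[i, , drop = FALSE]
    out <- data.frame(core_id = cc$core_id[1], tumor_id = cc$tumor_id[1],
                      patient_id = cc$patient_id[1], phenotype = cc$phenotype[1],
                      n_cells = nrow(cc), stringsAsFactors = FALSE)
    for (mk in MARKERS) {
      out[[paste0("h_", mk)]] <- h_score(cc, mk)
      out[[paste0("pos_", mk)]] <- positive_fraction(cc, mk)
    }
    for (pr in MARKER_PAIRS) {
      lab <- pair_label(pr)
      out[[paste0("copos_", lab)]] <- copositive_fraction(cc, pr)
      out[[paste0("coneg_", lab)]] <- conegative_fraction(cc, pr)
    }
    out$triple_pos <- copositive_fraction(cc, MARKERS)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tumor-level summaries by averaging cores
#'
#' Each metric is the unweighted mean of the tumor's cores (triplicate
#' cores averaged to one value per tumor site).
#'
#' @param core_summary output of [summarize_cores()].
#' @return data.frame, one row per tumor, with `n_cores` and the averaged
#'   metric columns.
#' @export
summarize_tumors <- function(core_summary) {
  if (nrow(core_summary) == 0) stop("no cores to summarize", call. = FALSE)
  metric_cols <- setdiff(names(core_summary),
                         c("core_id", "tumor_id", "patient_id", "phenotype"))
  idx <- split(seq_len(nrow(core_summary)), core_summary$tumor_id)
  rows <- lapply(idx, function(i) {
    cs <- core_summary[i, , drop = FALSE]
    out <- data.frame(tumor_id = cs$tumor_id[1], patient_id = cs$patient_id[1],
                      phenotype = cs$phenotype[1], n_cores = nrow(cs),
                      stringsAsFactors = FALSE)
    for (m in metric_cols) out[[m]] <- mean(cs[[m]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify tumors as double-positive for each marker pair
#'
#' A tumor is double-positive for a pair when its core-averaged
#' co-positive fraction reaches the threshold `tau` (inclusive: a fraction
#' exactly at the threshold is positive). The conventional threshold is
#' 20% of cells co-staining.
#'
#' @param tumor_summary output of [summarize_tumors()].
#' @param tau positivity threshold in (0, 1); default 0.20.
#' @return `tumor_summary` with added logical columns `dp_<pair>` (and
#'   `tp_all` for triple positivity).
#' @export
classify_double_positive <- function(tumor_summary, tau = 0.20) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0, tau < 1)
  for (pr in MARKER_PAIRS) {
    lab <- pair_label(pr)
    tumor_summary[[paste0("dp_", lab)]] <-
      tumor_summary[[paste0("copos_", lab)]] >= tau
  }
  tumor_summary$tp_all <- tumor_summary$triple_pos >= tau
  tumor_summary
}

#' Patient roll-up and cohort positivity percentages
#'
#' Aggregates tumor-level double-positive calls to patients (number of
#' positive tumors, any-positive, all-positive) and to cohort percentages
#' per marker pair, overall and within each phenotype. Percentages are
#' reported rounded to one decimal; counts are exact.
#'
#' @param tumor_summary output of [summarize_tumors()], with or without
#'   the `dp_*` columns (added at `tau` if absent).
#' @param tau positivity threshold, see [classify_double_positive()].
#' @return list with `patients` (one row per patient per pair) and
#'   `cohort` (per pair x phenotype stratum: n_positive, n_total, pct,
#'   plus patient-level counts for the overall stratum).
#' @export
patient_rollup <- function(tumor_summary, tau = 0.20) {
  if (!all(paste0("dp_", vapply(MARKER_PAIRS, pair_label, character(1))) %in%
           names(tumor_summary))) {
    tumor_summary <- classify_double_positive(tumor_summary, tau)
  }
  pairs <- vapply(MARKER_PAIRS, pair_label, character(1))

  pat_rows <- list()
  for (lab in pairs) {
    flag <- tumor_summary[[paste0("dp_", lab)]]
    agg_n <- tapply(flag, tumor_summary$patient_id, length)
    agg_p <- tapply(flag, tumor_summary$patient_id, sum)
    pat_rows[[lab]] <- data.frame(
      patient_id = names(agg_n), pair = lab,
      n_tumors = as.integer(agg_n), n_positive_tumors = as.integer(agg_p),
      any_positive = as.integer(agg_p) > 0,
      all_positive = as.integer(agg_p) == as.integer(agg_n),
      stringsAsFactors = FALSE)
  }
  patients <- do.call(rbind, pat_rows)
  rownames(patients) <- NULL

  strata <- c(overall = NA_character_, stats::setNames(PHENOTYPES, PHENOTYPES))
  coh_rows <- list()
  for (lab in pairs) {
    flag <- tumor_summary[[paste0("dp_", lab)]]
    for (snm in names(strata)) {
      keep <- if (is.na(strata[[snm]])) rep(TRUE, nrow(tumor_summary)) else
        tumor_summary$phenotype == strata[[snm]]
      n_tot <- sum(keep); n_pos <- sum(flag[keep])
      if (n_tot == 0) next
      pp <- patients[patients$pair == lab, ]
      coh_rows[[paste(lab, snm)]] <- data.frame(
        pair = lab, stratum = snm,
        n_positive_tumors = n_pos, n_tumors = n_tot,
        pct_tumors = pct1(n_pos, n_tot),
        n_patients_any = if (snm == "overall") sum(pp$any_positive) else NA_integer_,
        n_patients_all = if (snm == "overall") sum(pp$all_positive) else NA_integer_,
        n_patients = if (snm == "overall") nrow(pp) else NA_integer_,
        pct_patients_any = if (snm == "overall")
          pct1(sum(pp$any_positive), nrow(pp)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, coh_rows)
  rownames(cohort) <- NULL
  list(patients = patients, cohort = cohort)
}

#' Pairwise phenotype comparisons of tumor-level values
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum tests between every pair of
#' phenotype groups, with Holm's step-down adjustment across the
#' comparisons. The exact null distribution is enumerated when the
#' combined sample size is at most 10 and there are no ties; otherwise
#' the normal approximation with midranks and tie-corrected variance is
#' used.
#'
#' @param values numeric vector (e.g. tumor-averaged H-scores).
#' @param groups grouping factor/character of the same length.
#' @return data.frame with one row per group pair: sample sizes, rank-sum
#'   statistic, raw and Holm-adjusted p-values.
#' @export
compare_phenotypes <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes == 0)) stop("a group has zero observations", call. = FALSE)

  combos <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(combos, function(gp) {
    x <- values[groups == gp[1]]; y <- values[groups == gp[2]]
    exact <- (length(x) + length(y)) <= 10
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    p <- wt$p.value
    # complete ties carry no rank information: report p = 1
    if (is.na(p) || is.nan(p)) p <- 1
    data.frame(group1 = gp[1], group2 = gp[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
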