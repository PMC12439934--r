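test_that("generator is deterministic for a fixed seed", {
  cfg <- mif_sim_config(n_patients = 4, tumors_per_patient = 2,
                        cells_per_core = 40, seed = 11L)
  a <- gen_mif_dataset(cfg)
  b <- gen_mif_dataset(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
})

test_that("perfect coupling makes every positive cell double-positive", {
  cfg <- mif_sim_config(n_patients = 4, tumors_per_patient = 2,
                        cells_per_core = 500,
                        marker_model = flat_marker_model(
                          c(b7h3 = 0.3, psma = 0.3, steap1 = 0.3)),
                        copositivity_coupling = 1,
                        tumor_sd = 0, core_sd = 0, seed = 5L)
  d <- gen_mif_dataset(cfg)
  # comonotone markers: intersection equals each marginal
  pos1 <- d$cells$b7h3_class >= 1
  pos2 <- d$cells$psma_class >= 1
  expect_identical(pos1, pos2)
  expect_equal(unique(d$truth$copos_b7h3_psma), 0.3, tolerance = 1e-9)
  # empirical marginal near 0.30 (3 binomial SE)
  se <- sqrt(0.3 * 0.7 / nrow(d$cells))
  expect_lt(abs(mean(pos1) - 0.3), 3 * se)
})

test_that("independent markers give product co-positivity", {
  cfg <- mif_sim_config(n_patients = 6, tumors_per_patient = 2,
                        cells_per_core = 500,
                        marker_model = flat_marker_model(
                          c(b7h3 = 0.4, psma = 0.5, steap1 = 0.3)),
                        copositivity_coupling = 0,
                        tumor_sd = 0, core_sd = 0, seed = 6L)
  d <- gen_mif_dataset(cfg)
  expect_equal(unique(d$truth$copos_b7h3_psma), 0.20, tolerance = 1e-9)
  emp <- mean(d$cells$b7h3_class >= 1 & d$cells$psma_class >= 1)
  se <- sqrt(0.2 * 0.8 / nrow(d$cells))
  expect_lt(abs(emp - 0.20), 3 * se)
})

test_that("cohort structure matches configuration", {
  cfg <- mif_sim_config(n_patients = 58, tumors_per_patient = 3,
                        cores_per_tumor = 3, cells_per_core = 20, seed = 2L)
  d <- gen_mif_dataset(cfg)
  n_tumors <- length(unique(d$cells$tumor_id))
  expect_equal(n_tumors, 58 * 3)
  expect_equal(length(unique(d$cells$core_id)), n_tumors * 3)
  expect_equal(length(unique(d$cells$patient_id)), 58)
  expect_equal(nrow(d$cells), n_tumors * 3 * 20)
  expect_equal(nrow(d$truth), n_tumors)
})

test_that("marginal positivity converges to configured values", {
  pos <- c(b7h3 = 0.45, psma = 0.6, steap1 = 0.25)
  cfg <- mif_sim_config(n_patients = 5, tumors_per_patient = 3,
                        cells_per_core = 400,
                        marker_model = flat_marker_model(pos),
                        copositivity_coupling = 0.4,
                        tumor_sd = 0, core_sd = 0, seed = 3L)
  d <- gen_mif_dataset(cfg)
  for (mk in names(pos)) {
    emp <- mean(d$cells[[paste0(mk, "_class")]] >= 1)
    se <- sqrt(pos[[mk]] * (1 - pos[[mk]]) / nrow(d$cells))
    expect_lt(abs(emp - pos[[mk]]), 3 * se)
  }
})

test_that("generated and true co-positive fractions obey Frechet bounds", {
  for (rho in c(-0.3, 0, 0.6, 1)) {
    cfg <- mif_sim_config(n_patients = 3, tumors_per_patient = 2,
                          cells_per_core = 200,
                          copositivity_coupling = rho, seed = 7L)
    d <- gen_mif_dataset(cfg)
    tr <- d$truth
    for (pr in adcsynergy:::MARKER_PAIRS) {
      lab <- adcsynergy:::pair_label(pr)
      p1 <- tr[[paste0("pos_", pr[1])]]
      p2 <- tr[[paste0("pos_", pr[2])]]
      cp <- tr[[paste0("copos_", lab)]]
      expect_true(all(cp <= pmin(p1, p2) + 1e-8))
      expect_true(all(cp >= pmax(0, p1 + p2 - 1) - 1e-8))
      expect_true(all(tr$triple_pos <= cp + 1e-8))
    }
  }
})

test_that("invalid configurations are rejected", {
  bad_mm <- flat_marker_model()
  bad_mm[["AR+/NE-"]]$b7h3 <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(mif_sim_config(marker_model = bad_mm), "sum to 1")
  expect_error(mif_sim_config(copositivity_coupling = -0.9), "-0.5")
  expect_error(mif_sim_config(phenotype_mix = c("AR+/NE-" = 1)), "named")
  expect_error(mif_sim_config(cells_per_core = 0), "whole number")
})
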