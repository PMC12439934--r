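test_that("default screen layout matches the 384-well design", {
  cfg <- screen_sim_config(seed = 1L)
  expect_equal(length(cfg$combo_agents), 13)
  sc <- gen_screen_plate(cfg)
  pl <- sc$plates[["C4-2B"]]
  expect_equal(nrow(pl), 384)
  combo_wells <- sum(!is.na(pl$agent2))
  expect_equal(combo_wells, choose(13, 2) * 3)   # 78 pairs in triplicate
  expect_equal(nrow(sc$truth$combos) / length(cfg$cell_lines), 78)
  expect_equal(sum(pl$control == "vehicle"), 6)
  expect_equal(sum(pl$control == "positive"), 6)
  expect_true(all(pl$rlu > 0))
  # deterministic for fixed seed
  sc2 <- gen_screen_plate(cfg)
  expect_identical(sc$plates, sc2$plates)
})

test_that("noise-free wells carry exactly baseline * (1 - effect)", {
  panel <- default_payload_panel()
  eff <- matrix(0.5, nrow(panel), 2,
                dimnames = list(panel$agent, c("L1", "L2")))
  cfg <- screen_sim_config(cell_lines = c("L1", "L2"), single_effects = eff,
                           noise_cv = 0, seed = 2L)
  sc <- gen_screen_plate(cfg)
  pl <- sc$plates$L1
  veh <- mean(pl$rlu[pl$control == "vehicle"])
  low <- pl$rlu[pl$control == "none" & is.na(pl$agent2) &
                  pl$dose_level == "low"]
  expect_equal(unique(low), veh / 2, tolerance = 1e-12)
  # combination wells at the Bliss null: e = 0.5 + 0.5 - 0.25 = 0.75
  cw <- pl$rlu[!is.na(pl$agent2)]
  expect_equal(unique(cw), veh * 0.25, tolerance = 1e-12)
})

test_that("interaction map must reference combination-arm agents", {
  expect_error(
    screen_sim_config(interaction_map = data.frame(
      agent1 = "A02", agent2 = "A03", excess = 0.2)),
    "outside the combination arm")
})

test_that("plate normalization anchors vehicle at 0 and positive control at 1", {
  trt <- data.frame(agent1 = c("A1", "A2", "A3"), agent2 = NA_character_,
                    dose_level = "low", rlu = c(100, 0.1, 50.05),
                    stringsAsFactors = FALSE)
  eff <- normalize_plate(make_plate(trt, mu_veh = 100, mu_pos = 0.1))
  e <- setNames(eff$effect, eff$agent1)
  expect_equal(unname(e["A1"]), 0)
  expect_equal(unname(e["A2"]), 1)
  expect_equal(unname(e["A3"]), 0.5, tolerance = 1e-12)
  # affine invariance: rescaling every RLU leaves effects unchanged
  pl2 <- make_plate(transform(trt, rlu = rlu * 37), mu_veh = 3700,
                    mu_pos = 3.7)
  expect_equal(normalize_plate(pl2)$effect, eff$effect, tolerance = 1e-12)
  # degenerate controls
  expect_error(normalize_plate(make_plate(trt, mu_veh = 1, mu_pos = 10)),
               "degenerate")
})

test_that("bliss_expected has null, absorbing and bound properties", {
  expect_equal(bliss_expected(0.4, 0.5), 0.7)
  expect_equal(bliss_expected(0, 0.37), 0.37)
  expect_equal(bliss_expected(1, 0.2), 1)
  expect_error(bliss_expected(1.2, 0.5), "\\[0, 1\\]")
  set.seed(8)
  e1 <- runif(100); e2 <- runif(100)
  b <- bliss_expected(e1, e2)
  expect_equal(b, bliss_expected(e2, e1))
  expect_true(all(b >= pmax(e1, e2) - 1e-12 & b <= 1))
})

test_that("nomination recovers an implanted pair and applies the MoA filter", {
  panel <- default_payload_panel()
  lines <- c("L1", "L2", "L3")
  eff <- matrix(0.45, nrow(panel), 3, dimnames = list(panel$agent, lines))
  imap <- data.frame(agent1 = "A01", agent2 = "A11", excess = 0.25)
  cfg <- screen_sim_config(cell_lines = lines, single_effects = eff,
                           interaction_map = imap, noise_cv = 0, seed = 3L)
  sc <- gen_screen_plate(cfg)
  effects <- do.call(rbind, lapply(sc$plates, normalize_plate))
  noms <- nominate_pairs(effects, panel, delta = 0.10, min_lines = 2)
  hit <- noms[noms$nominated, ]
  expect_equal(nrow(hit), 1)
  expect_equal(sort(c(hit$agent1, hit$agent2)), c("A01", "A11"))
  expect_equal(hit$n_lines_supporting, 3)
  # ranked first by total excess
  expect_equal(noms$agent1[1], "A01")
  # Bliss-null screen nominates nothing
  cfg0 <- screen_sim_config(cell_lines = lines, single_effects = eff,
                            noise_cv = 0, seed = 4L)
  eff0 <- do.call(rbind, lapply(gen_screen_plate(cfg0)$plates, normalize_plate))
  expect_false(any(nominate_pairs(eff0, panel, delta = 0.10)$nominated))
})

test_that("pairs within one pharmacological subgroup are never nominated", {
  # custom panel in which both combo agents share a subgroup
  panel <- data.frame(agent = c("X1", "X2"), class = "DDD",
                      subgroup = "topo1_inhibitor", combo_member = TRUE,
                      stringsAsFactors = FALSE)
  eff <- matrix(0.4, 2, 2, dimnames = list(panel$agent, c("L1", "L2")))
  cfg <- screen_sim_config(panel = panel, cell_lines = c("L1", "L2"),
                           single_effects = eff,
                           interaction_map = data.frame(
                             agent1 = "X1", agent2 = "X2", excess = 0.3),
                           noise_cv = 0, seed = 5L)
  effects <- do.call(rbind, lapply(gen_screen_plate(cfg)$plates,
                                   normalize_plate))
  noms <- nominate_pairs(effects, panel, delta = 0.10, min_lines = 2)
  expect_true(all(!noms$nominated))
  expect_gt(noms$max_excess[1], 0.10)   # excluded by MoA, not by excess
})

test_that("missing single-agent effects raise a data-integrity error", {
  effects <- data.frame(cell_line = "L1", agent1 = c("A01", "A01"),
                        agent2 = c(NA, "A11"),
                        dose_level = "low", n_wells = 1,
                        viability = 0.5, effect = 0.5, log10_rlu = 5,
                        stringsAsFactors = FALSE)
  expect_error(nominate_pairs(effects, default_payload_panel()),
               "missing low-dose single-agent effect")
})
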