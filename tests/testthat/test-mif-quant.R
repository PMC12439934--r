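test_that("H-score combines intensity and frequency on the 0-300 scale", {
  expect_equal(h_score(make_cells(b7h3 = rep(3, 10)), "b7h3"), 300)
  expect_equal(h_score(make_cells(b7h3 = rep(0, 10)), "b7h3"), 0)
  # 25% weak, 50% moderate, 25% negative -> 1*25 + 2*50 = 125
  expect_equal(h_score(make_cells(b7h3 = c(1, 2, 2, 0)), "b7h3"), 125)
  expect_error(h_score(make_cells()[0, ], "b7h3"), "empty")
})

test_that("positive fraction pools weak or stronger staining", {
  expect_equal(positive_fraction(make_cells(psma = c(1, 1, 1, 0)), "psma"), 0.75)
  expect_equal(positive_fraction(make_cells(psma = rep(0, 5)), "psma"), 0)
  cells <- make_cells(psma = c(0, 1, 2, 3, 0, 2))
  expect_equal(positive_fraction(cells, "psma"),
               1 - mean(cells$psma_class == 0))
})

test_that("co-positive fraction counts joint positivity", {
  toy <- make_cells(b7h3 = c(1, 1, 0, 0), psma = c(2, 0, 1, 0))
  expect_equal(copositive_fraction(toy, c("b7h3", "psma")), 0.25)
  expect_equal(conegative_fraction(toy, c("b7h3", "psma")), 0.25)
  disjoint <- make_cells(b7h3 = c(1, 1, 0, 0), psma = c(0, 0, 1, 1))
  expect_equal(copositive_fraction(disjoint, c("b7h3", "psma")), 0)
  triple <- make_cells(b7h3 = 1, psma = c(1, 0), steap1 = 1)
  expect_equal(copositive_fraction(triple, c("b7h3", "psma", "steap1")), 0.5)
})

test_that("tumor summaries average cores unweightedly and stay in range", {
  cells <- rbind(
    make_cells(b7h3 = c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0), psma = 1,
               core = "T1_C1"),
    make_cells(b7h3 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), psma = 1,
               core = "T1_C2"))
  cs <- summarize_cores(cells)
  expect_equal(nrow(cs), 2)
  ts <- summarize_tumors(cs)
  expect_equal(ts$pos_b7h3, mean(cs$pos_b7h3))
  expect_true(ts$pos_b7h3 >= min(cs$pos_b7h3) && ts$pos_b7h3 <= max(cs$pos_b7h3))
  # single core -> identity
  one <- summarize_tumors(cs[1, ])
  expect_equal(one$copos_b7h3_psma, cs$copos_b7h3_psma[1])
  # explicit two-core average
  cs2 <- cs; cs2$copos_b7h3_psma <- c(0.10, 0.30)
  expect_equal(summarize_tumors(cs2)$copos_b7h3_psma, 0.20)
})

test_that("tumor double-positive classification is inclusive at threshold", {
  ts <- data.frame(tumor_id = "T1", patient_id = "P1", phenotype = "AR+/NE-",
                   copos_b7h3_psma = 0.20, copos_b7h3_steap1 = 0.199,
                   copos_psma_steap1 = 1.0, triple_pos = 0.05)
  out <- classify_double_positive(ts, tau = 0.20)
  expect_true(out$dp_b7h3_psma)
  expect_false(out$dp_b7h3_steap1)
  expect_true(out$dp_psma_steap1)
  expect_false(out$tp_all)
})

test_that("patient roll-up counts and percentages are correct", {
  # 3 patients: P1 has 2 tumors (1 positive), P2 has 1 positive tumor,
  # P3 all negative
  ts <- data.frame(
    tumor_id = paste0("T", 1:4),
    patient_id = c("P1", "P1", "P2", "P3"),
    phenotype = c("AR+/NE-", "AR+/NE-", "AR+/NE-", "AR-/NE+"),
    copos_b7h3_psma = c(0.30, 0.10, 0.25, 0.05),
    copos_b7h3_steap1 = 0, copos_psma_steap1 = 0, triple_pos = 0,
    stringsAsFactors = FALSE)
  roll <- patient_rollup(ts, tau = 0.20)
  p <- roll$patients[roll$patients$pair == "b7h3_psma", ]
  expect_equal(p$n_positive_tumors[p$patient_id == "P1"], 1L)
  expect_true(p$any_positive[p$patient_id == "P2"])
  expect_false(p$all_positive[p$patient_id == "P1"])
  ch <- roll$cohort
  ov <- ch[ch$pair == "b7h3_psma" & ch$stratum == "overall", ]
  expect_equal(ov$n_positive_tumors, 2L)
  expect_equal(ov$pct_tumors, pct1(2, 4))
  expect_equal(ov$n_patients_any, 2L)
  expect_equal(ov$pct_patients_any, pct1(2, 3))
  # all-negative pair: zero percentages, no patient flagged
  ov0 <- ch[ch$pair == "b7h3_steap1" & ch$stratum == "overall", ]
  expect_equal(ov0$pct_tumors, 0)
  expect_equal(ov0$n_patients_any, 0L)
})

test_that("phenotype comparisons use exact rank-sum and Holm adjustment", {
  vals <- c(1, 2, 3, 4)
  grp <- c("a", "a", "b", "b")
  out <- compare_phenotypes(vals, grp)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  expect_equal(out$p, wilcox_exact_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)
  # identical groups -> p = 1 under the tie-handling convention
  out2 <- compare_phenotypes(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(out2$p, 1)
  # Holm-adjusted p's are monotone and >= raw
  set.seed(42)
  vals3 <- c(rnorm(6), rnorm(6, 2), rnorm(6, 4))
  grp3 <- rep(c("x", "y", "z"), each = 6)
  out3 <- compare_phenotypes(vals3, grp3)
  expect_true(all(out3$p_adj >= out3$p))
  ord <- order(out3$p)
  expect_true(all(diff(out3$p_adj[ord]) >= -1e-12))
  expect_error(compare_phenotypes(1:3, rep("a", 3)), "two groups")
})

test_that("H-score and positivity invariants hold on random cores", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    cells <- make_cells(b7h3 = sample(0:3, n, replace = TRUE),
                        psma = sample(0:3, n, replace = TRUE),
                        steap1 = sample(0:3, n, replace = TRUE))
    for (mk in c("b7h3", "psma", "steap1")) {
      h <- h_score(cells, mk)
      pf <- positive_fraction(cells, mk)
      expect_true(h >= 100 * pf - 1e-9 && h <= 300 + 1e-9)
    }
    cp <- copositive_fraction(cells, c("b7h3", "psma"))
    p1 <- positive_fraction(cells, "b7h3")
    p2 <- positive_fraction(cells, "psma")
    expect_true(cp <= min(p1, p2) + 1e-12)
    expect_true(cp >= max(0, p1 + p2 - 1) - 1e-12)
    tp <- copositive_fraction(cells, c("b7h3", "psma", "steap1"))
    expect_lte(tp, cp + 1e-12)
  }
})
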