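test_that("pair discordance straddles the threshold, inclusive on top", {
  expect_equal(pair_discordance(0.25, 0.15), 1L)
  expect_equal(pair_discordance(0.25, 0.30), 0L)
  expect_equal(pair_discordance(0.05, 0.10), 0L)
  expect_equal(pair_discordance(0.20, 0.19), 1L)   # boundary is positive
  expect_equal(pair_discordance(0.20, 0.20), 0L)
})

test_that("unit index equals exhaustive pair enumeration", {
  expect_equal(heterogeneity_index(c(0.25, 0.30, 0.15)), 2 / 3)
  expect_equal(heterogeneity_index(c(0.25, 0.15)), 1)
  expect_equal(heterogeneity_index(c(0.25, 0.3, 0.5)), 0)
  expect_true(is.na(heterogeneity_index(0.4)))
  set.seed(21)
  for (i in 1:50) {
    f <- runif(sample(2:8, 1))
    expect_equal(heterogeneity_index(f), het_index_oracle(f))
    # invariance to ordering and to monotone side-preserving transforms
    expect_equal(heterogeneity_index(sample(f)), heterogeneity_index(f))
    g <- function(x) 0.2 + (x - 0.2) * 0.5   # keeps side of tau = 0.2
    expect_equal(heterogeneity_index(pmin(1, pmax(0, g(f)))),
                 heterogeneity_index(f))
  }
})

test_that("pooled index averages informative units with bootstrap CI", {
  # all concordant -> 0 with degenerate CI
  hb <- heterogeneity_boot(rep(0.5, 8), rep(1:4, each = 2), B = 200, seed = 1)
  expect_equal(hb$point_estimate, 0)
  expect_equal(c(hb$ci_low, hb$ci_high), c(0, 0))
  # maximal discordance -> 1
  hb1 <- heterogeneity_boot(rep(c(0.1, 0.9), 4), rep(1:4, each = 2),
                            B = 200, seed = 1)
  expect_equal(hb1$point_estimate, 1)
  # indices {0, 1, 1, 0} -> 0.5, CI brackets it
  fr <- c(0.5, 0.5, 0.1, 0.9, 0.1, 0.9, 0.05, 0.05)
  hb2 <- heterogeneity_boot(fr, rep(1:4, each = 2), B = 500, seed = 3)
  expect_equal(hb2$point_estimate, 0.5)
  expect_true(hb2$ci_low <= 0.5 && hb2$ci_high >= 0.5)
  # singleton units are excluded; all-singleton input errors
  hb3 <- heterogeneity_boot(c(0.5, 0.1, 0.9), c(1, 2, 2), B = 200, seed = 1)
  expect_equal(hb3$n_units, 1L)
  expect_equal(hb3$n_excluded_units, 1L)
  expect_error(heterogeneity_boot(c(0.1, 0.9), c(1, 2), B = 200, seed = 1),
               "informative")
  expect_error(heterogeneity_boot(fr, rep(1:4, each = 2), B = 10, seed = 1),
               ">= 200")
})

test_that("bootstrap is deterministic for a fixed seed and CI shrinks with n", {
  fr <- rep(c(0.1, 0.3), 30)
  un <- rep(1:30, each = 2)
  a <- heterogeneity_boot(fr, un, B = 300, seed = 9)
  b <- heterogeneity_boot(fr, un, B = 300, seed = 9)
  expect_identical(a$ci_low, b$ci_low)
  widths <- vapply(c(10, 40, 160), function(n) {
    set.seed(100 + n)
    f <- runif(2 * n)
    u <- rep(seq_len(n), each = 2)
    hb <- heterogeneity_boot(f, u, B = 400, seed = 5)
    hb$ci_high - hb$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("pooled estimate recovers the generating discordance probability", {
  # fractions uniform on [0,1]: P(>= 0.2) = 0.8, so a pair is discordant
  # with probability 2 * 0.8 * 0.2 = 0.32 whatever the unit size
  set.seed(31)
  n_pat <- 58
  fr <- runif(n_pat * 3)
  un <- rep(seq_len(n_pat), each = 3)
  hb <- heterogeneity_boot(fr, un, B = 500, seed = 7)
  se <- stats::sd(hb$unit_indices) / sqrt(hb$n_units)
  expect_lt(abs(hb$point_estimate - 0.32), 3 * se)
})

test_that("heterogeneity table covers both levels and all pairs", {
  d <- gen_mif_dataset(mif_sim_config(n_patients = 10, tumors_per_patient = 3,
                                      cells_per_core = 60, seed = 13L))
  cs <- summarize_cores(d$cells)
  ts <- summarize_tumors(cs)
  ht <- heterogeneity_table(ts, cs, B = 300, seed = 2L)
  expect_equal(nrow(ht), 6)
  expect_setequal(unique(ht$level), c("intra_patient", "intra_tumoral"))
  expect_true(all(ht$ci_low <= ht$estimate & ht$estimate <= ht$ci_high))
})
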