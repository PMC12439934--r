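# Small in-code fixtures shared across tests.

# Build a cell table from per-marker class vectors (recycled to the
# longest length).
make_cells <- function(b7h3 = 0, psma = 0, steap1 = 0,
                       core = "T1_C1", tumor = "T1", patient = "P1",
                       phenotype = "AR+/NE-") {
  n <- max(length(b7h3), length(psma), length(steap1))
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             core_id = core, tumor_id = tumor, patient_id = patient,
             phenotype = phenotype,
             b7h3_class = rep_len(b7h3, n),
             psma_class = rep_len(psma, n),
             steap1_class = rep_len(steap1, n),
             stringsAsFactors = FALSE)
}

# Marker model where every phenotype/marker has the same positive
# fraction `pos`, split over weak/moderate/strong.
flat_marker_model <- function(pos = c(b7h3 = 0.3, psma = 0.3, steap1 = 0.3)) {
  one <- function(p) c(1 - p, p * 0.5, p * 0.3, p * 0.2)
  mm <- lapply(adcsynergy:::PHENOTYPES, function(ph) {
    list(b7h3 = one(pos[["b7h3"]]), psma = one(pos[["psma"]]),
         steap1 = one(pos[["steap1"]]))
  })
  names(mm) <- adcsynergy:::PHENOTYPES
  mm
}

# Minimal plate with explicit control wells and one treated well per row
# of `trt` (data.frame agent1, agent2, dose_level, rlu).
make_plate <- function(trt, mu_veh = 100, mu_pos = 0.1, cell_line = "L1",
                       n_ctrl = 3) {
  ctrl <- data.frame(agent1 = NA_character_, agent2 = NA_character_,
                     dose_level = NA_character_,
                     control = rep(c("vehicle", "positive"), each = n_ctrl),
                     rlu = rep(c(mu_veh, mu_pos), each = n_ctrl),
                     stringsAsFactors = FALSE)
  trt$control <- "none"
  pl <- rbind(trt[, c("agent1", "agent2", "dose_level", "control", "rlu")],
              ctrl)
  pl$well <- sprintf("A%02d", seq_len(nrow(pl)))
  attr(pl, "cell_line") <- cell_line
  pl
}

# Exhaustive pair-enumeration oracle for the heterogeneity index.
het_index_oracle <- function(fractions, tau = 0.20) {
  n <- length(fractions)
  if (n < 2) return(NA_real_)
  prs <- utils::combn(n, 2)
  mean(vapply(seq_len(ncol(prs)), function(k) {
    adcsynergy::pair_discordance(fractions[prs[1, k]], fractions[prs[2, k]],
                                 tau)
  }, numeric(1)))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments
# (no ties assumed).
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  all_w <- apply(utils::combn(n, m), 2, function(i) {
    sum(r[i]) - m * (m + 1) / 2
  })
  mean_w <- m * (n - m) / 2
  mean(abs(all_w - mean_w) >= abs(w_obs - mean_w) - 1e-12)
}
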