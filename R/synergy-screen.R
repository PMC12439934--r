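#' Bliss-independence expected effect
#'
#' Expected fraction affected of a combination under independent drug
#' action: `e1 + e2 - e1*e2`. Symmetric, monotone in each argument and
#' bounded by `[max(e1, e2), 1]`.
#'
#' @param e1,e2 fractions affected in \[0, 1\] (vectorized).
#' @return expected combined fraction affected.
#' @export
bliss_expected <- function(e1, e2) {
  assert_prob(e1); assert_prob(e2)
  e1 + e2 - e1 * e2
}

#' Normalize a screen plate to fractions affected
#'
#' Control-anchored normalization: relative viability
#' `v = (rlu - mean(positive)) / (mean(vehicle) - mean(positive))`,
#' clipped to \[0, 1\], so vehicle-level signal maps to effect 0 and
#' positive-control (maximal kill) signal to effect 1. Replicate wells
#' are averaged after normalization; `log10(rlu)` of the averaged raw
#' signal is carried along for reporting. The normalization is invariant
#' to rescaling all luminescence values by a constant.
#'
#' @param plate plate data.frame (well, agent1, agent2, dose_level,
#'   control, rlu) with the cell line in attribute `cell_line` or a
#'   `cell_line` column.
#' @return data.frame with one row per condition: cell_line, agent1,
#'   agent2, dose_level, n_wells, viability, effect, log10_rlu.
#' @export
normalize_plate <- function(plate) {
  stopifnot(all(c("agent1", "agent2", "dose_level", "control", "rlu") %in%
                names(plate)))
  line <- attr(plate, "cell_line")
  if (is.null(line)) line <- plate$cell_line[1]
  if (is.null(line)) line <- NA_character_
  veh <- plate$rlu[plate$control == "vehicle"]
  pos <- plate$rlu[plate$control == "positive"]
  if (length(veh) < 1 || length(pos) < 1) {
    stop("plate must contain vehicle and positive control wells", call. = FALSE)
  }
  mu_veh <- mean(veh); mu_pos <- mean(pos)
  if (mu_veh <= mu_pos) {
    stop("degenerate controls: vehicle mean must exceed positive-control mean",
         call. = FALSE)
  }
  trt <- plate[plate$control == "none", , drop = FALSE]
  v <- pmin(1, pmax(0, (trt$rlu - mu_pos) / (mu_veh - mu_pos)))
  key <- paste(trt$agent1, ifelse(is.na(trt$agent2), "", trt$agent2),
               trt$dose_level, sep = "|")
  idx <- split(seq_len(nrow(trt)), key)
  rows <- lapply(idx, function(i) {
    data.frame(cell_line = line,
               agent1 = trt$agent1[i[1]], agent2 = trt$agent2[i[1]],
               dose_level = trt$dose_level[i[1]], n_wells = length(i),
               viability = mean(v[i]), effect = 1 - mean(v[i]),
               log10_rlu = log10(mean(trt$rlu[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nominate candidate synergistic pairs across cell lines
#'
#' Operationalizes "toxicity greater than the amplification of the
#' individual effects" as a Bliss excess: a pair is nominated when its
#' two agents act through different pharmacological subgroups and its
#' observed combination effect exceeds the Bliss expectation from the
#' agents' own low-dose effects by at least `delta` in at least
#' `min_lines` cell lines. Candidates are ranked by total excess summed
#' over all screened lines.
#'
#' @param effects row-bound [normalize_plate()] outputs across >= 2 lines.
#' @param panel mechanism-of-action annotation, see
#'   [default_payload_panel()].
#' @param delta minimum Bliss excess on the fraction-affected scale
#'   (default 0.10; a configuration choice, not a literature constant).
#' @param min_lines minimum number of supporting cell lines (default 2).
#' @return data.frame of all screened pairs sorted by decreasing total
#'   excess: agent1, agent2, subgroup1, subgroup2, n_lines,
#'   n_lines_supporting, total_excess, max_excess, nominated.
#' @export
nominate_pairs <- function(effects, panel = default_payload_panel(),
                           delta = 0.10, min_lines = 2) {
  stopifnot(delta >= 0, min_lines >= 1)
  sub_of <- stats::setNames(panel$subgroup, panel$agent)
  combos <- effects[!is.na(effects$agent2), , drop = FALSE]
  singles <- effects[is.na(effects$agent2) & effects$dose_level == "low", ,
                     drop = FALSE]
  if (nrow(combos) == 0) stop("no combination conditions in 'effects'",
                              call. = FALSE)
  key <- paste(combos$agent1, combos$agent2)
  rows <- lapply(split(seq_len(nrow(combos)), key), function(i) {
    a1 <- combos$agent1[i[1]]; a2 <- combos$agent2[i[1]]
    exc <- vapply(i, function(j) {
      line <- combos$cell_line[j]
      s1 <- singles$effect[singles$agent1 == a1 & singles$cell_line == line]
      s2 <- singles$effect[singles$agent1 == a2 & singles$cell_line == line]
      if (length(s1) != 1 || length(s2) != 1) {
        stop("missing low-dose single-agent effect for pair ", a1, "/", a2,
             " in line ", line, call. = FALSE)
      }
      combos$effect[j] - bliss_expected(s1, s2)
    }, numeric(1))
    data.frame(agent1 = a1, agent2 = a2,
               subgroup1 = unname(sub_of[a1]), subgroup2 = unname(sub_of[a2]),
               n_lines = length(i), n_lines_supporting = sum(exc >= delta),
               total_excess = sum(exc), max_excess = max(exc),
               nominated = unname(sub_of[a1] != sub_of[a2]) &&
                 sum(exc >= delta) >= min_lines,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_excess), ]
  rownames(out) <- NULL
  out
}
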