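#' @keywords internal
"_PACKAGE"

# Canonical marker and phenotype vocabularies used across the package.
MARKERS <- c("b7h3", "psma", "steap1")
MARKER_PAIRS <- list(c("b7h3", "psma"), c("b7h3", "steap1"), c("psma", "steap1"))
PHENOTYPES <- c("AR+/NE-", "AR+/NE+", "AR-/NE-", "AR-/NE+")

pair_label <- function(pair) paste(pair[1], pair[2], sep = "_")

#' Cohort percentage at the paper's reporting precision
#'
#' Percentage `100 * num / den` rounded to one decimal place, the convention
#' used for all cohort-level positivity summaries (e.g. "46/58 (79.3%)").
#' Internal computations always keep full precision; this helper is only the
#' reporting step.
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @return numeric percentage rounded to one decimal.
#' @examples
#' pct1(46, 58)   # 79.3
#' pct1(94, 146)  # 64.4
#' @export
pct1 <- function(num, den) {
  stopifnot(is.numeric(num), is.numeric(den), all(den > 0))
  round(100 * num / den, 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-stream seed for stage `k` of a run seeded with `seed`.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69621 + 1013 * k) %% 2147483629)
}

# Upper-orthant probability P(Z1 >= a, Z2 >= b) for standard bivariate
# normal with correlation rho. One-dimensional quadrature via the
# conditional decomposition Z2 | Z1 = z ~ N(rho z, 1 - rho^2).
bvn_upper <- function(a, b, rho) {
  stopifnot(rho >= -1, rho <= 1)
  if (rho == 1)  return(stats::pnorm(max(a, b), lower.tail = FALSE))
  if (rho == -1) return(max(0, stats::pnorm(-b) - stats::pnorm(a)))
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((b - rho * z) / s, lower.tail = FALSE)
  stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# Upper-orthant probability for an equicorrelated standard MVN: all
# components >= their thresholds. Handles k = 1, 2, 3 (the three markers).
# rho >= 0 uses the one-factor representation (1-D quadrature for any k);
# rho < 0 (valid down to -1/(k-1)) conditions on the first component.
mvn_upper_equicorr <- function(thresholds, rho) {
  k <- length(thresholds)
  if (k == 1) return(stats::pnorm(thresholds, lower.tail = FALSE))
  if (k == 2) return(bvn_upper(thresholds[1], thresholds[2], rho))
  stopifnot(k == 3, rho > -0.5, rho <= 1)
  if (rho == 1) return(stats::pnorm(max(thresholds), lower.tail = FALSE))
  if (rho >= 0) {
    sr <- sqrt(rho); s <- sqrt(1 - rho)
    f <- function(w) {
      p <- stats::dnorm(w)
      for (t in thresholds) p <- p * stats::pnorm((t - sr * w) / s, lower.tail = FALSE)
      p
    }
    return(stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  # negative rho: (Z2, Z3) | Z1 = z is bivariate normal with mean rho*z,
  # variance 1 - rho^2 and correlation rho / (1 + rho)
  s <- sqrt(1 - rho^2)
  rc <- rho / (1 + rho)
  f <- function(zv) {
    vapply(zv, function(z) {
      stats::dnorm(z) *
        bvn_upper((thresholds[2] - rho * z) / s, (thresholds[3] - rho * z) / s, rc)
    }, numeric(1))
  }
  stats::integrate(f, thresholds[1], Inf, rel.tol = 1e-8)$value
}

# Shared argument checks -------------------------------------------------

assert_prob <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be numeric in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a whole number >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_cells <- function(cells) {
  need <- c("cell_id", "core_id", "tumor_id", "patient_id", "phenotype",
            paste0(MARKERS, "_class"))
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cell table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) == 0) stop("empty cell table", call. = FALSE)
  invisible(cells)
}

marker_class_col <- function(marker) {
  marker <- match.arg(tolower(marker), MARKERS)
  paste0(marker, "_class")
}
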