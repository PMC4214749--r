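# Sentinel for -log10(p) when a zero-variance sample with mean != expected
# drives the t statistic to infinity: beyond the smallest representable
# double p (~1e-324), and flagged so downstream stages can exclude it.
NEGLOGP_FLOOR <- 350

#' Significance of pipeline similarity at one density
#'
#' One-sample t-test of the per-subject Dice coefficients against the chance
#' expectation at that density (the density itself). The two-tailed p-value
#' is computed in log space from the Student-t survival function, so values
#' down to p ~ 1e-300 and beyond (|t| of 30+ at n = 28 is routine near the
#' convergence peak) are represented without underflow.
#'
#' @param dcs Numeric vector of per-subject Dice coefficients (length >= 2).
#' @param expected Chance-level Dice coefficient (the network density).
#' @param log_base Base for the negative logarithm of p (default 10).
#' @return List with `t`, `p`, `neglogp` and `flagged`. A zero-variance
#'   sample with mean equal to `expected` gives `t = 0`, `p = 1`; with mean
#'   different from `expected` the t statistic is infinite, `neglogp` is set
#'   to the log-space floor (350 in base 10) and `flagged` is `TRUE` — such
#'   values are not t-test outcomes and are excluded from peak detection.
#' @export
significance_at_density <- function(dcs, expected, log_base = 10) {
  if (length(dcs) < 2L) stopf("need at least 2 subjects, got %d", length(dcs))
  s <- sig_core(mean(dcs), stats::sd(dcs), length(dcs), expected, log_base)
  list(t = s$t, p = s$p, neglogp = s$neglogp, flagged = s$flagged)
}

# Vectorised core: means/sds/expected may be vectors of equal length.
# Sample sds at or below `eps` are a constant sample up to rounding (Dice
# coefficients across subjects are multiples of 1/k, so any genuine spread
# is orders of magnitude larger) and are treated as exactly zero.
sig_core <- function(means, sds, n, expected, log_base = 10, eps = 1e-12) {
  df <- n - 1
  delta <- means - expected
  degen <- sds <= eps
  tval <- ifelse(degen, 0, delta / (sds / sqrt(n)))
  # two-tailed: log p = log 2 + log S(|t|; df), S the survival function
  logp <- log(2) + stats::pt(abs(tval), df = df, lower.tail = FALSE,
                             log.p = TRUE)
  logp <- pmin(logp, 0) # guard log(2) overshoot at t = 0
  neglogp <- -logp / log(log_base)
  flagged <- degen & abs(delta) > eps
  tval[flagged] <- sign(delta[flagged]) * Inf
  neglogp[flagged] <- NEGLOGP_FLOOR * log(10) / log(log_base)
  p <- exp(logp)
  p[flagged] <- 0
  list(t = tval, p = p, neglogp = neglogp, flagged = flagged)
}

# Stack per-subject dc_curve data frames into a subjects x densities matrix
# over k = 1..T (k = 0 is excluded: its chance expectation of 0 makes the
# null degenerate).
dc_table_from_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  ks <- curves[[1]]$k
  for (cv in curves) {
    if (!identical(cv$k, ks))
      stopf("subject curves cover different density grids")
  }
  keep <- ks >= 1L
  tab <- do.call(rbind, lapply(curves, function(cv) cv$dc[keep]))
  attr(tab, "k") <- ks[keep]
  tab
}

#' Bootstrap significance curve across densities
#'
#' For every density, tests the subjects' Dice coefficients against the
#' chance expectation ([significance_at_density()]) and bootstraps the
#' subjects (resampling with replacement, the same `n_boot` resample draws
#' reused across densities) to obtain the bootstrap mean and standard error
#' of the negative log p-value.
#'
#' @param dc_table Either a subjects-by-densities matrix of Dice coefficients
#'   with an integer attribute `"k"` giving the edge count per column, or a
#'   list of per-subject [dc_curve()] data frames (k = 0 is dropped).
#' @param n_boot Number of bootstrap resamples (default 1000);
#'   `0` skips the bootstrap and returns the point-estimate curve only.
#' @param seed Integer seed for the resampling stream.
#' @param log_base Base of the negative logarithm (default 10).
#' @return Object of class `convergence_curve`: list with `k`, `densities`,
#'   `t_stats`, `neglogp` (point estimate), `flagged`, `neglogp_boot_mean`,
#'   `neglogp_se`, `n_subjects`, `n_boot`, `seed`, `log_base`, and the
#'   detected `peak_k` / `peak_density` (see [find_peak()]).
#' @export
bootstrap_curve <- function(dc_table, n_boot = 1000, seed = 1, log_base = 10) {
  if (is.list(dc_table) && !is.matrix(dc_table))
    dc_table <- dc_table_from_curves(dc_table)
  k <- attr(dc_table, "k")
  if (is.null(k)) stopf("dc_table needs a 'k' attribute (edge count per column)")
  n <- nrow(dc_table)
  if (n < 2L) stopf("need at least 2 subjects, got %d", n)
  if (n_boot < 0) stopf("n_boot must be >= 0")
  n_nodes <- round((1 + sqrt(1 + 8 * max(k))) / 2)
  t_edges <- max(k)
  expected <- k / t_edges
  point <- sig_core(colMeans(dc_table), col_sds(dc_table), n, expected,
                    log_base)
  boot_mean <- rep(NA_real_, length(k))
  boot_se <- rep(NA_real_, length(k))
  boot_flagged <- rep(NA_real_, length(k))
  if (n_boot >= 1) {
    idx <- with_seed(seed,
                     matrix(sample.int(n, n * n_boot, replace = TRUE),
                            nrow = n_boot))
    for (j in seq_along(k)) {
      x <- matrix(dc_table[, j][idx], nrow = n_boot)
      m <- rowMeans(x)
      d <- x - m # recycles m down columns: centers each resample row
      s <- sig_core(m, sqrt(rowSums(d * d) / (n - 1)), n, expected[j],
                    log_base)
      boot_mean[j] <- mean(s$neglogp)
      boot_se[j] <- stats::sd(s$neglogp)
      boot_flagged[j] <- mean(s$flagged)
    }
  }
  curve <- structure(
    list(k = as.integer(k), densities = expected, t_stats = point$t,
         neglogp = point$neglogp, flagged = point$flagged,
         neglogp_boot_mean = boot_mean, neglogp_se = boot_se,
         boot_flagged_frac = boot_flagged, n_subjects = n, n_boot = as.integer(n_boot), seed = seed,
         log_base = log_base, n_nodes = n_nodes,
         peak_k = NA_integer_, peak_density = NA_real_),
    class = "convergence_curve")
  peak <- tryCatch(find_peak(curve), error = function(e) {
    warnf("peak detection: %s", conditionMessage(e))
    list(peak_k = NA_integer_, peak_density = NA_real_)
  })
  curve$peak_k <- peak$peak_k
  curve$peak_density <- peak$peak_density
  curve
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf(
    "<convergence_curve: %d densities, %d subjects, n_boot = %d, peak at k = %d (density %.3f)>\n",
    length(x$k), x$n_subjects, x$n_boot, x$peak_k, x$peak_density))
  invisible(x)
}

#' Locate the peak-convergence density
#'
#' Returns the density at which the point-estimate negative log p-value of
#' the similarity-vs-chance test attains its global maximum — the density at
#' which network similarity is most reliably different from random.
#' Boundary densities (k = 0 and k = T, where the chance expectation is
#' exactly 0 or 1 and the null degenerates) and flagged zero-variance
#' densities are excluded. Ties are broken toward the lower density (the
#' sparser, more specific network) with a warning.
#'
#' @param curve A `convergence_curve` from [bootstrap_curve()].
#' @param exclude_boundaries Drop k = 0 and k = T from the search (default).
#' @return List with `peak_k` and `peak_density`.
#' @export
find_peak <- function(curve, exclude_boundaries = TRUE) {
  stopifnot(inherits(curve, "convergence_curve"))
  k <- curve$k
  eligible <- !curve$flagged
  if (exclude_boundaries)
    eligible <- eligible & k > 0L & k < max(k)
  if (!any(eligible))
    stopf("no eligible densities for peak detection")
  y <- curve$neglogp
  best <- max(y[eligible])
  hits <- which(eligible & y == best)
  if (length(hits) > 1L)
    warnf("peak significance tied at %d densities; taking the sparsest",
          length(hits))
  at <- hits[1]
  list(peak_k = k[at], peak_density = curve$densities[at])
}
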