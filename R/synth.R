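#' Configuration for the synthetic cohort generator
#'
#' Describes a paired-pipeline, multi-scan cohort of synthetic fiber-density
#' connectomes with the statistical structure the convergence analysis
#' assumes: a hemisphere-symmetric planted core of true connections whose
#' latent weights are drawn from a high lognormal, a background of non-core
#' pairs drawn from a low lognormal, per-pipeline multiplicative
#' reconstruction noise, per-pipeline exact zeroing of a fraction of non-core
#' pairs (the tie mass at zero typical of probabilistic tractography
#' matrices), and per-scan acquisition noise shared by both pipelines
#' (both pipelines reconstruct the same repeat scans).
#'
#' @param n_nodes Even node count (default 34, the common merged atlas scale).
#' @param n_subjects Number of subjects (default 28, a typical cohort size).
#' @param n_scans Repeat scans per subject (default 3).
#' @param core_density Planted-core density in (0, 1) (default 0.196, a
#'   typical peak-convergence density at the 34-node scale).
#' @param signal_lognormal `c(meanlog, sdlog)` of core-edge latent weights.
#' @param noise_lognormal `c(meanlog, sdlog)` of non-core latent weights.
#' @param pipeline_noise_sd SD of per-pipeline multiplicative log-noise
#'   (default 0.22, which calibrates the inter-pipeline rank correlation of
#'   subject-mean networks to roughly 0.67 under the other defaults, matching
#'   the 0.6-0.7 range typical of independent tractography pipelines; see
#'   [calibrate_noise()]).
#' @param scan_noise_sd SD of per-scan multiplicative log-noise (default 0.3).
#' @param zero_fraction Fraction of non-core pairs zeroed per pipeline and
#'   subject, in `[0, 1)` (default 0.15; probabilistic tractography matrices
#'   at coarse node scales are densely populated, with a modest mass of
#'   exactly-zero, randomly-ranked pairs).
#' @param seed Master integer seed; every subject/scan/pipeline draws from a
#'   deterministic substream, so enlarging the cohort never perturbs
#'   existing subjects.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 34, n_subjects = 28, n_scans = 3,
                         core_density = 0.196,
                         signal_lognormal = c(meanlog = 3, sdlog = 0.5),
                         noise_lognormal = c(meanlog = 0, sdlog = 0.3),
                         pipeline_noise_sd = 0.22,
                         scan_noise_sd = 0.3,
                         zero_fraction = 0.15,
                         seed = 1) {
  if (n_nodes < 4 || n_nodes %% 2 != 0)
    stopf("n_nodes must be an even number >= 4 (hemisphere-symmetric core)")
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (n_scans < 1) stopf("n_scans must be >= 1")
  if (!(core_density > 0 && core_density < 1))
    stopf("core_density must be in (0, 1)")
  if (!(zero_fraction >= 0 && zero_fraction < 1))
    stopf("zero_fraction must be in [0, 1)")
  if (pipeline_noise_sd < 0 || scan_noise_sd < 0)
    stopf("noise SDs must be non-negative")
  t_edges <- n_possible_edges(n_nodes)
  if (core_density * t_edges < 1)
    stopf("degenerate config: core_density * T = %.3f < 1 planted edge",
          core_density * t_edges)
  structure(
    list(n_nodes = as.integer(n_nodes), n_subjects = as.integer(n_subjects),
         n_scans = as.integer(n_scans), core_density = core_density,
         signal_lognormal = unname(signal_lognormal[1:2]),
         noise_lognormal = unname(noise_lognormal[1:2]),
         pipeline_noise_sd = pipeline_noise_sd,
         scan_noise_sd = scan_noise_sd,
         zero_fraction = zero_fraction, seed = as.integer(seed)),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config: %d nodes, %d subjects x %d scans, core density %.3f, pipeline noise sd %.3g, zero fraction %.2f, seed %d>\n",
    x$n_nodes, x$n_subjects, x$n_scans, x$core_density, x$pipeline_noise_sd,
    x$zero_fraction, x$seed))
  invisible(x)
}

# Synthetic hemisphere-interleaved parcellation scheme: lh_r01, rh_r01, ...
synth_scheme <- function(n_nodes) {
  m <- n_nodes / 2
  lobes <- c("temporal", "frontal", "parietal", "occipital", "insula",
             "limbic/cingulate")
  region <- sprintf("r%02d", seq_len(m))
  parcellation_scheme(
    sprintf("synth%d", n_nodes),
    labels = as.vector(rbind(paste0("lh_", region), paste0("rh_", region))),
    hemisphere = rep(c("L", "R"), m),
    lobe = rep(rep(lobes, length.out = m), each = 2))
}

# Planted hemisphere-symmetric core: sample mirror-orbits of node pairs until
# exactly k_core edges are placed. Orbits are homotopic pairs (size 1) or
# mirror pairs of edges (size 2).
planted_core_edges <- function(n_nodes, k_core, seed) {
  m <- n_nodes / 2
  lh <- function(r) 2L * r - 1L
  rh <- function(r) 2L * r
  orbits <- list()
  for (r in seq_len(m)) orbits[[length(orbits) + 1L]] <- cbind(lh(r), rh(r))
  if (m >= 2) {
    for (r in seq_len(m - 1)) {
      for (s in seq(r + 1L, m)) {
        orbits[[length(orbits) + 1L]] <-
          rbind(c(lh(r), lh(s)), c(rh(r), rh(s)))
        orbits[[length(orbits) + 1L]] <-
          rbind(c(lh(r), rh(s)), c(rh(r), lh(s)))
      }
    }
  }
  ord <- with_seed(seed, sample.int(length(orbits)))
  chosen <- matrix(integer(0), 0, 2)
  remaining <- k_core
  for (o in ord) {
    sz <- nrow(orbits[[o]])
    if (sz <= remaining) {
      chosen <- rbind(chosen, orbits[[o]])
      remaining <- remaining - sz
      if (remaining == 0L) break
    }
  }
  if (remaining > 0L) {
    # all homotopic orbits spent; take one half of an unused mirror orbit
    warnf("planted core not perfectly hemisphere-symmetric (1 unpaired edge)")
    for (o in ord) {
      sz <- nrow(orbits[[o]])
      cand <- orbits[[o]][1, , drop = FALSE]
      key <- cand[, 1] + n_nodes * (cand[, 2] - 1)
      if (sz == 2 && !(key %in% (chosen[, 1] + n_nodes * (chosen[, 2] - 1)))) {
        chosen <- rbind(chosen, cand)
        break
      }
    }
  }
  i <- pmin(chosen[, 1], chosen[, 2])
  j <- pmax(chosen[, 1], chosen[, 2])
  sort(i + n_nodes * (j - 1L)) # canonical upper-triangle linear indices
}

#' Generate a paired-pipeline synthetic cohort
#'
#' Draws, per subject, latent edge weights (lognormal: high for planted-core
#' edges, low otherwise), observes them through two pipelines (independent
#' multiplicative log-noise and independent zeroing of a fraction of non-core
#' pairs per pipeline) and through repeat scans (per-scan log-noise shared by
#' both pipelines). All draws come from substreams derived from `cfg$seed`,
#' so the cohort is fully reproducible and per-subject stable.
#'
#' @param cfg A [synth_config()].
#' @return List with `pipeline1` and `pipeline2` (each a list over subjects
#'   of lists over scans of [weighted_network()]s), `truth` (the planted core
#'   as a [binary_network()]), `scheme`, and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  scheme <- synth_scheme(cfg$n_nodes)
  t_edges <- n_possible_edges(cfg$n_nodes)
  k_core <- max(1L, as.integer(round(cfg$core_density * t_edges)))
  core_idx <- planted_core_edges(cfg$n_nodes, k_core, derive_seed(cfg$seed, 7))
  ut <- ut_index(cfg$n_nodes)
  is_core <- ut %in% core_idx
  n_noncore <- sum(!is_core)
  n_zero <- as.integer(floor(cfg$zero_fraction * n_noncore))

  truth <- binary_from_edges(scheme, core_idx)
  assemble <- function(w) {
    W <- matrix(0, cfg$n_nodes, cfg$n_nodes)
    W[ut] <- w
    weighted_network(scheme, W + t(W))
  }

  p1 <- vector("list", cfg$n_subjects)
  p2 <- vector("list", cfg$n_subjects)
  for (subj in seq_len(cfg$n_subjects)) {
    latent <- with_seed(derive_seed(cfg$seed, 11, subj), {
      w <- numeric(t_edges)
      w[is_core] <- stats::rlnorm(k_core, cfg$signal_lognormal[1],
                                  cfg$signal_lognormal[2])
      w[!is_core] <- stats::rlnorm(n_noncore, cfg$noise_lognormal[1],
                                   cfg$noise_lognormal[2])
      w
    })
    pipe_obs <- lapply(1:2, function(pipe) {
      with_seed(derive_seed(cfg$seed, 13, subj, pipe), {
        eps <- stats::rnorm(t_edges) * cfg$pipeline_noise_sd
        w <- latent * exp(eps)
        if (n_zero > 0) {
          zero_at <- sample(which(!is_core), n_zero)
          w[zero_at] <- 0
        }
        w
      })
    })
    scan_noise <- lapply(seq_len(cfg$n_scans), function(scan) {
      with_seed(derive_seed(cfg$seed, 17, subj, scan),
                exp(stats::rnorm(t_edges) * cfg$scan_noise_sd))
    })
    p1[[subj]] <- lapply(scan_noise, function(sn) assemble(pipe_obs[[1]] * sn))
    p2[[subj]] <- lapply(scan_noise, function(sn) assemble(pipe_obs[[2]] * sn))
  }
  list(pipeline1 = p1, pipeline2 = p2, truth = truth, scheme = scheme,
       config = cfg)
}

#' Subject-mean networks of a synthetic cohort
#'
#' Averages each subject's repeat-scan networks per pipeline
#' (see [average_scans()]).
#'
#' @param cohort Output of [generate_cohort()].
#' @return List with `p1` and `p2`: lists of per-subject [weighted_network()]s.
#' @export
subject_mean_networks <- function(cohort) {
  list(p1 = lapply(cohort$pipeline1, average_scans),
       p2 = lapply(cohort$pipeline2, average_scans))
}

#' Calibrate pipeline noise to a target inter-pipeline rank correlation
#'
#' Adjusts `pipeline_noise_sd` by bisection until the mean Spearman
#' correlation between the two pipelines' subject-mean networks, simulated
#' over `n_reps` Monte-Carlo subjects, is within `tol` of `target`. The same
#' random substreams are reused at every candidate SD (the noise SD only
#' scales standard-normal draws), so the simulated correlation is a smooth,
#' monotone decreasing function of the SD and bisection is well posed.
#'
#' @param target Target mean Spearman correlation, in (0, 1).
#' @param cfg A [synth_config()]; all fields except `pipeline_noise_sd` and
#'   `n_subjects` are taken as given.
#' @param n_reps Monte-Carlo subjects per evaluation (default 50).
#' @param tol Acceptable |achieved - target| (default 0.05).
#' @param sd_max Upper end of the bisection bracket (default 4).
#' @return The config with `pipeline_noise_sd` set to the calibrated value;
#'   the achieved correlation is attached as attribute `"achieved_spearman"`.
#'   Errors if the target lies outside the achievable range, reporting that
#'   range.
#' @export
calibrate_noise <- function(target, cfg, n_reps = 50, tol = 0.05, sd_max = 4) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!(target > 0 && target < 1))
    stopf("target Spearman must be in (0, 1); shared positive latent weights force it above 0")
  eval_rho <- function(sd) {
    cfg2 <- cfg
    cfg2$pipeline_noise_sd <- sd
    cfg2$n_subjects <- as.integer(n_reps)
    sm <- subject_mean_networks(generate_cohort(cfg2))
    mean(vapply(seq_len(n_reps), function(s)
      weight_correlations(sm$p1[[s]], sm$p2[[s]])$spearman, numeric(1)))
  }
  lo <- 0; hi <- sd_max
  rho_lo <- eval_rho(lo) # highest achievable (least noise)
  rho_hi <- eval_rho(hi)
  if (target > rho_lo + tol || target < rho_hi - tol)
    stopf("target Spearman %.3f unattainable: achievable range [%.3f, %.3f] for pipeline_noise_sd in [0, %g]",
          target, rho_hi, rho_lo, sd_max)
  sd_best <- lo; rho_best <- rho_lo
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    rho <- eval_rho(mid)
    if (abs(rho - target) < abs(rho_best - target)) {
      sd_best <- mid; rho_best <- rho
    }
    if (abs(rho - target) <= tol / 2 || (hi - lo) < 1e-4) break
    if (rho > target) lo <- mid else hi <- mid
  }
  if (abs(rho_best - target) > tol)
    stopf("calibration did not reach target %.3f (best %.3f at sd %.4g)",
          target, rho_best, sd_best)
  out <- cfg
  out$pipeline_noise_sd <- sd_best
  attr(out, "achieved_spearman") <- rho_best
  out
}
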