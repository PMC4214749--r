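#' Configuration of an end-to-end consensus analysis run
#'
#' Bundles the input mode, paths, seed and analysis settings for
#' [run_pipeline()]. Exactly one input mode is used:
#'
#' * `"synthetic"` — generate a cohort with [generate_cohort()] from `synth`
#'   (its seed is derived from the master `seed`);
#' * `"matrices"` — read per-scan weighted matrices from a table
#'   `matrices(subject, pipeline, scan, path)`;
#' * `"endpoints"` — build networks from fiber endpoint records via a table
#'   `endpoints(subject, pipeline, scan, endpoints_path, volumes_path)`.
#'
#' @param mode One of `"synthetic"`, `"matrices"`, `"endpoints"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed for every stochastic stage (tie-breaking,
#'   bootstrap, synthetic generation).
#' @param synth A [synth_config()] (synthetic mode).
#' @param matrices,endpoints Data frames as described above.
#' @param scheme A [parcellation_scheme()] or path to a scheme TSV
#'   (matrices / endpoints modes).
#' @param merge_table Optional [correspondence_table()] or path: merge nodes
#'   to a common scale before analysis.
#' @param merge_volumes Optional named volume vector for count-mode merging.
#' @param n_boot Bootstrap resamples for the significance curve (default 1000).
#' @param log_base Base of the negative log p (default 10).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "matrices", "endpoints"),
                       out_dir, seed, synth = synth_config(),
                       matrices = NULL, endpoints = NULL, scheme = NULL,
                       merge_table = NULL, merge_volumes = NULL,
                       n_boot = 1000, log_base = 10) {
  mode <- match.arg(mode)
  if (missing(seed)) stopf("a master seed is mandatory")
  if (mode == "matrices" && is.null(matrices))
    stopf("matrices mode needs a 'matrices' table")
  if (mode == "endpoints" && is.null(endpoints))
    stopf("endpoints mode needs an 'endpoints' table")
  if (mode != "synthetic" && is.null(scheme))
    stopf("%s mode needs a scheme", mode)
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         synth = synth, matrices = matrices, endpoints = endpoints,
         scheme = scheme, merge_table = merge_table,
         merge_volumes = merge_volumes, n_boot = n_boot,
         log_base = log_base),
    class = "run_config")
}

stage_error <- function(stage, subject, e) {
  stopf("pipeline stage '%s' failed%s: %s", stage,
        if (is.null(subject)) "" else sprintf(" (subject %s)", subject),
        conditionMessage(e))
}

#' Run the full consensus analysis
#'
#' Executes construction (or loading/generation), optional node merging,
#' scan averaging, the all-density Dice curve per subject, the bootstrap
#' significance curve with peak detection, and consensus-network extraction
#' with graph metrics. Writes per-stage artifacts (JSON/TSV/GraphML) and a
#' manifest with the config echo, seeds, package version and MD5 checksums
#' of every artifact; re-running with an identical config reproduces the
#' checksums bitwise.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: inputs -> per subject x pipeline x scan weighted networks
  scheme <- cfg$scheme
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  nets <- switch(cfg$mode,
    synthetic = {
      sc <- cfg$synth
      sc$seed <- derive_seed(cfg$seed, 101)
      coh <- tryCatch(generate_cohort(sc),
                      error = function(e) stage_error("synthetic", NULL, e))
      scheme <- coh$scheme
      list(p1 = coh$pipeline1, p2 = coh$pipeline2)
    },
    matrices = {
      tab <- cfg$matrices
      load_one <- function(subject, pipeline) {
        rows <- tab[tab$subject == subject & tab$pipeline == pipeline, ]
        lapply(rows$path, function(p)
          tryCatch(read_weight_matrix(p, scheme),
                   error = function(e) stage_error(
                     sprintf("read matrix '%s'", p), subject, e)))
      }
      subjects <- sort(unique(tab$subject))
      list(p1 = lapply(subjects, load_one, pipeline = 1),
           p2 = lapply(subjects, load_one, pipeline = 2))
    },
    endpoints = {
      tab <- cfg$endpoints
      build_one <- function(subject, pipeline) {
        rows <- tab[tab$subject == subject & tab$pipeline == pipeline, ]
        lapply(seq_len(nrow(rows)), function(r)
          tryCatch(build_weighted_network(
            read_fiber_endpoints(rows$endpoints_path[r], rows$volumes_path[r]),
            scheme),
            error = function(e) stage_error("construct", subject, e)))
      }
      subjects <- sort(unique(tab$subject))
      list(p1 = lapply(subjects, build_one, pipeline = 1),
           p2 = lapply(subjects, build_one, pipeline = 2))
    })

  # --- stage: optional merge to a common node scale
  if (!is.null(cfg$merge_table)) {
    mt <- cfg$merge_table
    if (is.character(mt)) mt <- read_correspondence(mt)
    merge_all <- function(pl) lapply(pl, function(scans)
      lapply(scans, function(net)
        tryCatch(merge_nodes(net, mt, cfg$merge_volumes),
                 error = function(e) stage_error("merge", NULL, e))))
    nets$p1 <- merge_all(nets$p1)
    nets$p2 <- merge_all(nets$p2)
    scheme <- nets$p1[[1]][[1]]$scheme
  }

  # --- stage: scan averaging
  mean1 <- lapply(seq_along(nets$p1), function(s)
    tryCatch(average_scans(nets$p1[[s]]),
             error = function(e) stage_error("average_scans", s, e)))
  mean2 <- lapply(seq_along(nets$p2), function(s)
    tryCatch(average_scans(nets$p2[[s]]),
             error = function(e) stage_error("average_scans", s, e)))
  n_sub <- length(mean1)

  # --- stage: all-density Dice curves
  curves <- lapply(seq_len(n_sub), function(s)
    tryCatch(dc_curve(mean1[[s]], mean2[[s]], seed = derive_seed(cfg$seed, 202),
                      subject = s),
             error = function(e) stage_error("dc_curve", s, e)))
  correlations <- lapply(seq_len(n_sub), function(s)
    suppressWarnings(weight_correlations(mean1[[s]], mean2[[s]])))

  # --- stage: significance curve, bootstrap, peak
  curve <- tryCatch(
    bootstrap_curve(curves, n_boot = cfg$n_boot,
                    seed = derive_seed(cfg$seed, 303),
                    log_base = cfg$log_base),
    error = function(e) stage_error("bootstrap_curve", NULL, e))

  # --- stage: consensus extraction at the peak density
  thr_seed <- derive_seed(cfg$seed, 202)
  bins1 <- lapply(seq_len(n_sub), function(s)
    threshold_by_rank(mean1[[s]], curve$peak_k, derive_seed(thr_seed, s, 1L)))
  bins2 <- lapply(seq_len(n_sub), function(s)
    threshold_by_rank(mean2[[s]], curve$peak_k, derive_seed(thr_seed, s, 2L)))
  consensus <- tryCatch(consensus_edges(bins1, bins2),
                        error = function(e) stage_error("consensus", NULL, e))

  # --- stage: artifacts + manifest
  paths <- list(
    curve = file.path(cfg$out_dir, "convergence_curve.json"),
    consensus = file.path(cfg$out_dir, "consensus.json"),
    graphml = file.path(cfg$out_dir, "consensus.graphml"),
    prevalence = file.path(cfg$out_dir, "prevalence.tsv"),
    metrics = file.path(cfg$out_dir, "metrics_table.tsv"))
  write_result_json(curve, paths$curve)
  write_result_json(
    list(peak_k = consensus$peak_k, n_subjects = consensus$n_subjects,
         intersection_edges = consensus$intersection$k,
         mean_dc_at_peak = mean(vapply(
           seq_len(n_sub), function(s) dice(bins1[[s]], bins2[[s]]),
           numeric(1))),
         spearman = vapply(correlations, `[[`, numeric(1), "spearman"),
         pearson = vapply(correlations, `[[`, numeric(1), "pearson"),
         metrics_summary = consensus$metrics$summary),
    paths$consensus)
  write_graphml(consensus, paths$graphml)
  write_prevalence(consensus, paths$prevalence)
  write_metrics_table(consensus, paths$metrics)

  manifest <- list(
    mode = cfg$mode, seed = cfg$seed, n_subjects = n_sub,
    n_nodes = scheme$N, n_boot = cfg$n_boot, log_base = cfg$log_base,
    peak_k = curve$peak_k, peak_density = curve$peak_density,
    package_version = as.character(utils::packageVersion("netconsensus")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
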