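#' Consensus network at the peak-convergence density
#'
#' Given every subject's two pipeline networks thresholded at the same edge
#' count (the peak-convergence density), computes per subject the convergent
#' edge set (the intersection of the two pipelines' edges), the per-edge
#' prevalence (fraction of subjects whose convergent set contains the edge)
#' and the group intersection network (edges convergent in every subject,
#' i.e. prevalence exactly 1). Optionally attaches the per-subject,
#' per-pipeline graph-metric table of the thresholded networks.
#'
#' @param p1_bins,p2_bins Lists of per-subject [binary_network()]s on the
#'   same scheme and with equal `k` (one per pipeline).
#' @param metrics If `TRUE` (default), compute [metrics_table()] of the
#'   thresholded subject networks.
#' @return Object of class `consensus_result`: list with `scheme`, `peak_k`,
#'   `n_subjects`, `prevalence` (symmetric N-by-N matrix in `[0, 1]`),
#'   `intersection` ([binary_network()]), `subject_convergent` (list of
#'   per-subject convergent [binary_network()]s) and, when requested,
#'   `metrics`.
#' @export
consensus_edges <- function(p1_bins, p2_bins, metrics = TRUE) {
  if (length(p1_bins) != length(p2_bins) || !length(p1_bins))
    stopf("need the same positive number of subject networks per pipeline")
  n_sub <- length(p1_bins)
  ref <- p1_bins[[1]]
  for (b in c(p1_bins, p2_bins)) {
    stopifnot(inherits(b, "binary_network"))
    check_same_scheme(ref, b)
    if (b$k != ref$k)
      stopf("all networks must share the peak edge count: k = %d vs %d",
            ref$k, b$k)
  }
  n <- ref$scheme$N
  prev <- matrix(0, n, n)
  subject_convergent <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    conv <- p1_bins[[s]]$A * p2_bins[[s]]$A
    subject_convergent[[s]] <- binary_network(ref$scheme, conv)
    prev <- prev + conv
  }
  prev <- prev / n_sub
  dimnames(prev) <- dimnames(ref$A)
  inter <- binary_network(ref$scheme, (prev == 1) * 1L)
  out <- list(scheme = ref$scheme, peak_k = ref$k, n_subjects = n_sub,
              prevalence = prev, intersection = inter,
              subject_convergent = subject_convergent)
  if (metrics) out$metrics <- metrics_table(p1_bins, p2_bins)
  structure(out, class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result: %d subjects at k = %d; %d edges in every subject's pipeline intersection>\n",
    x$n_subjects, x$peak_k, x$intersection$k))
  invisible(x)
}

#' Write the per-edge prevalence matrix as TSV
#'
#' @param res A `consensus_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prevalence <- function(res, path) {
  stopifnot(inherits(res, "consensus_result"))
  df <- data.frame(label = rownames(res$prevalence), res$prevalence,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the metrics summary as TSV
#'
#' One row per pipeline with columns PL, CC, G.Eff, L.Eff, AS formatted as
#' mean and sd columns.
#'
#' @param res A `consensus_result` computed with `metrics = TRUE`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(res, path) {
  stopifnot(inherits(res, "consensus_result"), !is.null(res$metrics))
  s <- res$metrics$summary
  wide <- stats::reshape(
    s[, c("pipeline", "metric", "mean", "sd")],
    direction = "wide", idvar = "pipeline", timevar = "metric")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
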