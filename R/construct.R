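#' Build a fiber-density weighted network from endpoint records
#'
#' The connection weight between two distinct parcels i and j is the density
#' of connecting fibers: the number of fibers whose two end-points terminated
#' in i and j, divided by the mean total seed (boundary) voxel volume of the
#' two parcels, `(V_i + V_j) / 2`. Fibers with both end-points in the same
#' parcel do not connect two distinct parcels and are discarded (tallied in
#' the result's `construction` attribute).
#'
#' @param ep A [fiber_endpoints()] object.
#' @param scheme A [parcellation_scheme()]. Every scheme label must have a
#'   volume in `ep$volumes`.
#' @param permissive If `TRUE`, fibers touching a label absent from the scheme
#'   are tallied and dropped instead of raising an error.
#' @return A [weighted_network()] with a `construction` attribute listing
#'   `discarded_intra` (same-parcel fibers), `discarded_unknown` (unknown-label
#'   fibers, permissive mode) and the volume reading used.
#' @export
build_weighted_network <- function(ep, scheme, permissive = FALSE) {
  stopifnot(inherits(ep, "fiber_endpoints"),
            inherits(scheme, "parcellation_scheme"))
  labels <- scheme$nodes$label
  missing_vol <- setdiff(labels, names(ep$volumes))
  if (length(missing_vol))
    stopf("no boundary-voxel volume for parcel(s): %s",
          paste(missing_vol, collapse = ", "))
  V <- ep$volumes[labels]
  a <- ep$records$parcel_a
  b <- ep$records$parcel_b
  known <- a %in% labels & b %in% labels
  if (!all(known)) {
    offenders <- unique(c(a[!known], b[!known]))
    offenders <- setdiff(offenders, labels)
    if (!permissive)
      stopf("fiber endpoints reference label(s) not in scheme '%s': %s",
            scheme$name, paste(offenders, collapse = ", "))
  }
  ai <- match(a[known], labels)
  bi <- match(b[known], labels)
  intra <- ai == bi
  C <- matrix(0, scheme$N, scheme$N)
  if (any(!intra)) {
    i <- pmin(ai[!intra], bi[!intra])
    j <- pmax(ai[!intra], bi[!intra])
    # column-major linear index i + N (j - 1), i < j, is an upper-tri index
    tab <- tabulate(match(i + scheme$N * (j - 1), ut_index(scheme$N)),
                    nbins = length(ut_index(scheme$N)))
    C[ut_index(scheme$N)] <- tab
    C <- C + t(C)
  }
  pair_mean_vol <- (outer(V, V, "+")) / 2
  W <- C / pair_mean_vol
  diag(W) <- 0
  net <- weighted_network(scheme, W)
  attr(net, "construction") <- list(
    discarded_intra = sum(intra),
    discarded_unknown = sum(!known),
    volume_reading = "pair mean of total boundary-voxel volumes, (V_i + V_j)/2")
  net
}

#' Average a subject's repeat-scan networks
#'
#' The subject-level weighted network is the elementwise arithmetic mean of
#' the per-scan weighted networks.
#'
#' @param nets List of [weighted_network()]s on the same scheme (>= 1).
#' @return A [weighted_network()].
#' @export
average_scans <- function(nets) {
  if (!length(nets)) stopf("need at least one network to average")
  do.call(check_same_scheme, nets)
  W <- Reduce(`+`, lapply(nets, `[[`, "W")) / length(nets)
  weighted_network(nets[[1]]$scheme, W)
}

#' Merge network nodes to a coarser scale
#'
#' Aggregates the nodes of a weighted network according to an atlas
#' correspondence table (e.g. Desikan-Killiany 68 -> common 34 scale).
#' With parcel volumes supplied ("count mode"), fiber counts are recovered
#' from the density weights, pooled between merged groups, volumes summed
#' within groups, and the fiber-density formula re-applied — this commutes
#' exactly with [build_weighted_network()] on pre-merged endpoints.
#' Without volumes, weights are summed between groups (a documented
#' approximation: densities are not additive across parcels of different
#' sizes). Either way, connections internal to a merged group become
#' self-connections and are dropped; the pooled count (or weight) lost this
#' way is reported in the `merge` attribute.
#'
#' @param net A [weighted_network()].
#' @param table A [correspondence_table()] covering all scheme labels.
#' @param volumes Optional named vector of boundary-voxel volumes (mm^3) for
#'   every source parcel; switches on count mode.
#' @return A [weighted_network()] on the merged scheme, with a `merge`
#'   attribute (`mode`, `discarded_intra_group`).
#' @export
merge_nodes <- function(net, table, volumes = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  ms <- merged_scheme(net$scheme, table)
  n_tgt <- ms$scheme$N
  M <- matrix(0, net$scheme$N, n_tgt)
  M[cbind(seq_len(net$scheme$N), ms$group)] <- 1
  if (is.null(volumes)) {
    Wm <- t(M) %*% net$W %*% M
    discarded <- sum(diag(Wm)) / 2
    diag(Wm) <- 0
    out <- weighted_network(ms$scheme, Wm)
    attr(out, "merge") <- list(mode = "weight-sum",
                               discarded_intra_group = discarded)
    return(out)
  }
  labels <- net$scheme$nodes$label
  missing_vol <- setdiff(labels, names(volumes))
  if (length(missing_vol))
    stopf("merge in count mode: no volume for parcel(s): %s",
          paste(missing_vol, collapse = ", "))
  V <- volumes[labels]
  if (any(!is.finite(V)) || any(V <= 0))
    stopf("volumes must be strictly positive")
  C <- net$W * (outer(V, V, "+") / 2) # recover fiber counts
  Cm <- t(M) %*% C %*% M
  discarded <- sum(diag(Cm)) / 2
  diag(Cm) <- 0
  Vm <- as.numeric(t(M) %*% V)
  Wm <- Cm / (outer(Vm, Vm, "+") / 2)
  diag(Wm) <- 0
  out <- weighted_network(ms$scheme, Wm)
  attr(out, "merge") <- list(mode = "count-pool",
                             discarded_intra_group = discarded,
                             merged_volumes = stats::setNames(Vm, ms$scheme$nodes$label))
  out
}
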