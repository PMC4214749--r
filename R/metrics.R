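# All-pairs shortest-path lengths of a binary undirected graph by BFS.
# Returns an n x n numeric matrix, Inf for unreachable pairs, 0 diagonal.
bin_distances <- function(A) {
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[D[s, nxt] == Inf & nxt != s]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs with a finite
#' distance. Consensus networks at densities around 0.1-0.2 can be
#' disconnected, so unreachable pairs are excluded from the mean and their
#' count is reported in the `"unreachable_pairs"` attribute.
#'
#' @param net A [binary_network()].
#' @return Mean finite shortest-path length (`NaN` with a warning if the
#'   graph has no edges), with attribute `unreachable_pairs` (ordered pairs).
#' @export
characteristic_pathlength <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  D <- bin_distances(net$A)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  pl <- if (any(finite)) mean(off[finite]) else {
    warnf("characteristic path length undefined: no connected node pairs")
    NaN
  }
  structure(pl, unreachable_pairs = sum(!finite))
}

#' Clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `2 t_i / (d_i (d_i - 1))`, with `t_i` the number of triangles through node
#' i and `d_i` its degree. Nodes of degree < 2 have no possible triangles and
#' contribute 0 (a standard convention for binary brain networks).
#'
#' @param net A [binary_network()].
#' @return Mean clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$A * 1.0
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  mean(ci)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' `1 / Inf = 0` for unreachable pairs; the empty graph has efficiency 0.
#'
#' @param net A [binary_network()].
#' @return Global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  geff_from_adjacency(net$A)
}

geff_from_adjacency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bin_distances(A)
  inv <- 1 / D[row(D) != col(D)]
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours. Nodes with fewer than 2 neighbours contribute 0.
#'
#' @param net A [binary_network()].
#' @return Local efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$A
  vals <- vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    geff_from_adjacency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two endpoints of each edge,
#' every undirected edge contributing both orientations (the edge-degree
#' correlation formulation of degree mixing).
#'
#' @param net A [binary_network()] with at least one edge.
#' @return Assortativity coefficient in `[-1, 1]`; `NaN` with a warning when
#'   all edge-endpoint degrees are equal (e.g. regular graphs).
#' @export
assortativity <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (net$k < 1L) stopf("assortativity needs at least one edge")
  idx <- edge_indices(net)
  n <- net$scheme$N
  i <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  deg <- rowSums(net$A)
  x <- c(deg[i], deg[j]) # both orientations
  y <- c(deg[j], deg[i])
  if (stats::var(x) == 0) {
    warnf("assortativity undefined: zero variance of edge-endpoint degrees")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Graph metrics of one binary network
#'
#' @param net A [binary_network()].
#' @return Named list: `PL` (characteristic path length), `CC` (clustering
#'   coefficient), `Geff` (global efficiency), `Leff` (local efficiency),
#'   `AS` (assortativity), `unreachable_pairs`.
#' @export
network_metrics <- function(net) {
  pl <- characteristic_pathlength(net)
  as_val <- if (net$k >= 1L) suppressWarnings(assortativity(net)) else NaN
  list(PL = as.numeric(pl), CC = clustering_coefficient(net),
       Geff = global_efficiency(net), Leff = local_efficiency(net),
       AS = as_val,
       unreachable_pairs = attr(pl, "unreachable_pairs"))
}

#' Per-pipeline summary of subject network metrics
#'
#' Computes the five binary graph metrics for every subject's thresholded
#' network in each pipeline and summarises them as mean and sample standard
#' deviation per pipeline (the shape of a consensus-network properties
#' table). Undefined metrics (e.g. assortativity of a regular graph) are
#' dropped from the summary and counted.
#'
#' @param p1_bins,p2_bins Lists of per-subject [binary_network()]s for the
#'   two pipelines.
#' @return List with `per_subject` (data frame: pipeline, subject, metric
#'   columns) and `summary` (data frame: pipeline, metric, mean, sd, n,
#'   n_undefined).
#' @export
metrics_table <- function(p1_bins, p2_bins) {
  per_pipe <- function(bins, pipe) {
    rows <- lapply(seq_along(bins), function(s) {
      m <- network_metrics(bins[[s]])
      data.frame(pipeline = pipe, subject = s, PL = m$PL, CC = m$CC,
                 Geff = m$Geff, Leff = m$Leff, AS = m$AS,
                 unreachable_pairs = m$unreachable_pairs)
    })
    do.call(rbind, rows)
  }
  per_subject <- rbind(per_pipe(p1_bins, "P1"), per_pipe(p2_bins, "P2"))
  metric_names <- c("PL", "CC", "Geff", "Leff", "AS")
  summary_rows <- list()
  for (pipe in c("P1", "P2")) {
    sub <- per_subject[per_subject$pipeline == pipe, ]
    for (mn in metric_names) {
      vals <- sub[[mn]]
      ok <- is.finite(vals)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        pipeline = pipe, metric = mn,
        mean = if (any(ok)) mean(vals[ok]) else NA_real_,
        sd = if (sum(ok) > 1) stats::sd(vals[ok]) else
          if (sum(ok) == 1) 0 else NA_real_,
        n = sum(ok), n_undefined = sum(!ok))
    }
  }
  list(per_subject = per_subject, summary = do.call(rbind, summary_rows))
}
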