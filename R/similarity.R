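#' Rank connections of a weighted network with randomized tie-breaking
#'
#' Orders all T = N (N - 1) / 2 possible connections by decreasing weight.
#' Connections of equal weight (predominantly the exact zeros of probabilistic
#' tractography matrices) are assigned a random rank within their tie class,
#' drawn once per (network, seed) from a seeded stream. The ranking is reused
#' across all densities, so thresholded networks are nested: the edge set at
#' k is always a subset of the edge set at k + 1.
#'
#' @param net A [weighted_network()].
#' @param seed Integer seed for the tie-breaking stream.
#' @return Integer vector of length T: canonical edge indices (upper-triangle,
#'   column-major) in rank order, highest-weighted first.
#' @export
rank_connections <- function(net, seed) {
  stopifnot(inherits(net, "weighted_network"))
  w <- upper_weights(net)
  tie_break <- with_seed(seed, stats::runif(length(w)))
  order(-w, tie_break)
}

#' Threshold a weighted network at a retained edge count
#'
#' Produces the binary network containing the k highest ranked connections.
#' Connections strictly above the k-th weight are always included; within the
#' tied weight class at the boundary, members are chosen uniformly at random
#' from the seeded tie-breaking stream (see [rank_connections()]).
#'
#' @param net A [weighted_network()].
#' @param k Number of edges to retain, `0 <= k <= T`.
#' @param seed Integer seed for tie-breaking.
#' @return A [binary_network()] with exactly `k` edges.
#' @export
threshold_by_rank <- function(net, k, seed) {
  t_edges <- n_possible_edges(net$scheme$N)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0 || k > t_edges)
    stopf("k must be an integer in [0, %d], got %s", t_edges, format(k))
  ord <- rank_connections(net, seed)
  binary_from_edges(net$scheme, ut_index(net$scheme$N)[ord[seq_len(k)]])
}

#' Dice similarity between two equal-density binary networks
#'
#' The Dice coefficient is the proportion of intersecting connections
#' relative to the number of connections at that density:
#' `|edges(a) intersect edges(b)| / k`. It is defined for networks of equal
#' density only. For two uniformly random k-edge networks its expectation
#' equals the network density k / T, which is the chance reference used by
#' the convergence analysis. For `k = 0` both networks are identically empty
#' and the coefficient is 1 by convention.
#'
#' @param a,b [binary_network()]s on the same scheme with equal `k`.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_network"), inherits(b, "binary_network"))
  check_same_scheme(a, b)
  if (a$k != b$k)
    stopf("Dice coefficient requires equal density: k = %d vs %d", a$k, b$k)
  if (a$k == 0L) return(1)
  idx <- ut_index(a$scheme$N)
  sum(a$A[idx] == 1L & b$A[idx] == 1L) / a$k
}

#' Dice similarity curve across all densities
#'
#' Thresholds two weighted networks at every possible density k = 0..T using
#' one tie-broken ranking per network and computes the Dice coefficient, its
#' chance expectation (the density k / T) and the normalized value
#' (observed minus expected) at each k.
#'
#' Both rankings derive deterministically from `seed`; pass `subject` /
#' pipeline tags so each subject-by-pipeline combination gets an independent
#' substream of the cohort master seed.
#'
#' @param p1,p2 [weighted_network()]s on the same scheme.
#' @param seed Master integer seed.
#' @param subject Optional integer tag identifying the subject substream.
#' @return Data frame of class `dc_curve` with columns `k`, `density`, `dc`,
#'   `expected`, `normalized`, one row per k in 0..T.
#' @export
dc_curve <- function(p1, p2, seed, subject = 0L) {
  stopifnot(inherits(p1, "weighted_network"), inherits(p2, "weighted_network"))
  check_same_scheme(p1, p2)
  n <- p1$scheme$N
  t_edges <- n_possible_edges(n)
  ord1 <- rank_connections(p1, derive_seed(seed, subject, 1L))
  ord2 <- rank_connections(p2, derive_seed(seed, subject, 2L))
  # edge e enters the intersection at k = max(rank1(e), rank2(e))
  rank1 <- integer(t_edges); rank1[ord1] <- seq_len(t_edges)
  rank2 <- integer(t_edges); rank2[ord2] <- seq_len(t_edges)
  inter_at_k <- cumsum(tabulate(pmax(rank1, rank2), nbins = t_edges))
  k <- 0:t_edges
  dc <- c(1, inter_at_k / seq_len(t_edges)) # k = 0 convention: both empty
  expected <- k / t_edges
  out <- data.frame(k = k, density = expected, dc = dc, expected = expected,
                    normalized = dc - expected)
  class(out) <- c("dc_curve", "data.frame")
  out
}

#' Rank and weight correlation between two weighted networks
#'
#' Spearman (rank, mid-ranks for ties) and Pearson (weight) correlations over
#' the T upper-triangle weight pairs.
#'
#' @param p1,p2 [weighted_network()]s on the same scheme.
#' @return Named list `spearman`, `pearson`. If either weight vector has zero
#'   variance the correlations are undefined and returned as `NaN` with a
#'   warning.
#' @export
weight_correlations <- function(p1, p2) {
  stopifnot(inherits(p1, "weighted_network"), inherits(p2, "weighted_network"))
  check_same_scheme(p1, p2)
  w1 <- upper_weights(p1)
  w2 <- upper_weights(p2)
  if (stats::var(w1) == 0 || stats::var(w2) == 0) {
    warnf("weight correlations undefined: zero variance in a weight vector")
    return(list(spearman = NaN, pearson = NaN))
  }
  list(spearman = stats::cor(w1, w2, method = "spearman"),
       pearson = stats::cor(w1, w2, method = "pearson"))
}
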