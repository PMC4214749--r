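#' Weighted connectivity networks
#'
#' A weighted network holds the symmetric, non-negative N-by-N matrix of
#' fiber-density connection weights (connecting fibers per mm^3 of seed
#' boundary voxels) between all parcels of a scheme. The diagonal is zero:
#' fibers must terminate in two distinct parcels to count as a connection.
#'
#' @param scheme A [parcellation_scheme()].
#' @param W Numeric N-by-N matrix. Must be symmetric within `tol`, elementwise
#'   non-negative, zero diagonal. Dimnames, if present, must match the scheme
#'   labels (any order; the matrix is permuted into scheme order).
#' @param tol Symmetry tolerance; asymmetries up to `tol` are repaired by
#'   averaging `(W + t(W)) / 2`, anything larger is an error.
#' @return An object of class `weighted_network`: list with `scheme` and `W`
#'   (labelled, in scheme order).
#' @export
weighted_network <- function(scheme, W, tol = 1e-9) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  W <- as.matrix(W)
  n <- scheme$N
  if (!is.numeric(W) || nrow(W) != n || ncol(W) != n)
    stopf("W must be a numeric %d x %d matrix", n, n)
  if (!is.null(rownames(W))) {
    bad <- c(setdiff(rownames(W), scheme$nodes$label),
             setdiff(scheme$nodes$label, rownames(W)))
    if (length(bad))
      stopf("matrix labels do not match scheme '%s': %s", scheme$name,
            paste(unique(bad), collapse = ", "))
    if (!identical(rownames(W), colnames(W)))
      stopf("row and column labels differ")
    W <- W[scheme$nodes$label, scheme$nodes$label, drop = FALSE]
  }
  if (anyNA(W)) stopf("W contains missing values")
  asym <- max(abs(W - t(W)))
  if (asym > tol)
    stopf("W is asymmetric beyond tolerance (max |W - t(W)| = %.3g > %.3g)",
          asym, tol)
  W <- (W + t(W)) / 2
  if (min(W) < 0)
    stopf("W has negative entries (min = %.3g)", min(W))
  if (any(diag(W) != 0))
    stopf("W has nonzero diagonal entries")
  dimnames(W) <- list(scheme$nodes$label, scheme$nodes$label)
  structure(list(scheme = scheme, W = W), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  w <- upper_weights(x)
  cat(sprintf(
    "<weighted_network on '%s': %d nodes, %d/%d nonzero connections, max weight %.4g>\n",
    x$scheme$name, x$scheme$N, sum(w > 0), length(w), max(w)))
  invisible(x)
}

# Upper-triangle weight vector in canonical edge order.
upper_weights <- function(net) net$W[ut_index(net$scheme$N)]

#' Binary (thresholded) networks
#'
#' A binary network is a 0/1 adjacency at a stated retained edge count `k`;
#' its density is `k / T` with `T = N (N - 1) / 2`.
#'
#' @param scheme A [parcellation_scheme()].
#' @param A 0/1 N-by-N matrix, symmetric, zero diagonal.
#' @return Object of class `binary_network`: list with `scheme`, `A`, `k`,
#'   `density`.
#' @export
binary_network <- function(scheme, A) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  A <- as.matrix(A)
  n <- scheme$N
  if (nrow(A) != n || ncol(A) != n)
    stopf("A must be %d x %d", n, n)
  storage.mode(A) <- "integer"
  if (!all(A %in% c(0L, 1L))) stopf("A must contain only 0/1")
  if (!identical(A, t(A))) stopf("A must be symmetric")
  if (any(diag(A) != 0L)) stopf("A must have a zero diagonal")
  dimnames(A) <- list(scheme$nodes$label, scheme$nodes$label)
  k <- as.integer(sum(A[ut_index(n)]))
  structure(list(scheme = scheme, A = A, k = k,
                 density = k / n_possible_edges(n)),
            class = "binary_network")
}

# Build a binary network from canonical edge indices (upper-triangle linear).
binary_from_edges <- function(scheme, edge_idx) {
  n <- scheme$N
  A <- matrix(0L, n, n)
  A[edge_idx] <- 1L
  A <- A + t(A)
  binary_network(scheme, A)
}

# Canonical edge indices of a binary network.
edge_indices <- function(bin) {
  idx <- ut_index(bin$scheme$N)
  idx[bin$A[idx] == 1L]
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network on '%s': %d nodes, k = %d edges, density %.4g>\n",
              x$scheme$name, x$scheme$N, x$k, x$density))
  invisible(x)
}

#' Fiber endpoint records
#'
#' Tabular output of whole-brain probabilistic tractography after endpoint
#' assignment: one row per reconstructed fiber giving the two parcels its
#' end-point coordinates terminated in, plus the total seed (boundary) voxel
#' volume per parcel in mm^3.
#'
#' @param records Data frame with columns `fiber_id`, `parcel_a`, `parcel_b`.
#' @param volumes Named numeric vector: parcel label -> boundary-voxel volume
#'   (mm^3), strictly positive.
#' @return Object of class `fiber_endpoints`.
#' @export
fiber_endpoints <- function(records, volumes) {
  records <- as.data.frame(records)
  need <- c("fiber_id", "parcel_a", "parcel_b")
  if (!all(need %in% names(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  if (is.null(names(volumes)) || any(names(volumes) == ""))
    stopf("volumes must be a named vector (parcel label -> mm^3)")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stopf("boundary-voxel volumes must be strictly positive")
  records$parcel_a <- as.character(records$parcel_a)
  records$parcel_b <- as.character(records$parcel_b)
  structure(list(records = records, volumes = volumes),
            class = "fiber_endpoints")
}

#' @export
print.fiber_endpoints <- function(x, ...) {
  cat(sprintf("<fiber_endpoints: %d fibers, %d parcels with volumes>\n",
              nrow(x$records), length(x$volumes)))
  invisible(x)
}

#' Read fiber endpoint records
#'
#' @param endpoints_path TSV with columns `fiber_id`, `parcel_a`, `parcel_b`.
#' @param volumes_path TSV with columns `label`, `mm3`.
#' @return A [fiber_endpoints()].
#' @export
read_fiber_endpoints <- function(endpoints_path, volumes_path) {
  rec <- utils::read.delim(endpoints_path, stringsAsFactors = FALSE)
  vol <- utils::read.delim(volumes_path, stringsAsFactors = FALSE)
  if (!all(c("label", "mm3") %in% names(vol)))
    stopf("volumes table %s must have columns label, mm3", volumes_path)
  fiber_endpoints(rec, stats::setNames(vol$mm3, vol$label))
}

# shared guard: all networks on the same scheme
check_same_scheme <- function(...) {
  nets <- list(...)
  ref <- nets[[1]]$scheme
  for (net in nets[-1]) {
    if (net$scheme$N != ref$N ||
        !identical(net$scheme$nodes$label, ref$nodes$label))
      stopf("networks are not on the same parcellation scheme ('%s' vs '%s')",
            ref$name, net$scheme$name)
  }
  invisible(TRUE)
}
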