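# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's own code paths: distances come
# from igraph BFS, triangles from explicit enumeration, correlations from
# direct formulas.

toy_scheme <- function(n, name = sprintf("toy%d", n)) {
  parcellation_scheme(
    name,
    labels = paste0(rep(c("lh_", "rh_"), length.out = n), "p",
                    sprintf("%02d", seq_len(n))),
    hemisphere = rep(c("L", "R"), length.out = n),
    lobe = rep("frontal", n))
}

rand_weighted <- function(scheme, seed) {
  n <- scheme$N
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  weighted_network(scheme, W + t(W))
}

# all-equal weights: thresholding draws a uniformly random k-edge network
flat_weighted <- function(scheme) {
  n <- scheme$N
  W <- matrix(1, n, n)
  diag(W) <- 0
  weighted_network(scheme, W)
}

rand_binary <- function(scheme, p, seed) {
  n <- scheme$N
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  binary_network(scheme, A + t(A))
}

bn_from_pairs <- function(scheme, pairs) {
  A <- matrix(0L, scheme$N, scheme$N)
  for (pr in pairs) A[pr[1], pr[2]] <- A[pr[2], pr[1]] <- 1L
  binary_network(scheme, A)
}

oracle_distances <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(g)
}

oracle_pathlength <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) next
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_len(a - 1)) {
        if (A[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    vals[i] <- 2 * links / (d * (d - 1))
  }
  mean(vals)
}

oracle_geff <- function(A) {
  D <- oracle_distances(A)
  mean(1 / D[row(D) != col(D)])
}

oracle_leff <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    vals[i] <- oracle_geff(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_assortativity <- function(A) {
  idx <- which(upper.tri(A) & A == 1)
  n <- nrow(A)
  i <- ((idx - 1) %% n) + 1
  j <- ((idx - 1) %/% n) + 1
  deg <- rowSums(A)
  x <- c(deg[i], deg[j])
  y <- c(deg[j], deg[i])
  if (var(x) == 0) return(NaN)
  cor(x, y)
}

# pair-tally oracle for network construction: hash unordered label pairs
oracle_build <- function(records, volumes, labels) {
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(records))) {
    a <- records$parcel_a[r]
    b <- records$parcel_b[r]
    if (a == b) next
    W[a, b] <- W[a, b] + 1
    W[b, a] <- W[b, a] + 1
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) W[i, j] <- W[i, j] / ((volumes[labels[i]] + volumes[labels[j]]) / 2)
    }
  }
  W
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "netconsensus")
  if (p == "") p <- file.path("../../inst/extdata", f)
  p
}
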