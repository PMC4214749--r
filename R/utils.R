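# internal helpers shared across modules

# Linear indices of the strict upper triangle of an n x n matrix, column-major.
# This fixed enumeration is the canonical edge order used everywhere:
# edge t corresponds to the unordered node pair (i, j), i < j.
ut_index <- function(n) which(upper.tri(matrix(0L, n, n)))

# Number of possible undirected edges T = N (N - 1) / 2.
n_possible_edges <- function(n) as.integer(n * (n - 1L) / 2L)

# Map linear upper-triangle indices back to (i, j) node pairs, i < j.
ut_pairs <- function(n) {
  idx <- ut_index(n)
  cbind(row = ((idx - 1L) %% n) + 1L, col = ((idx - 1L) %/% n) + 1L)
}

#' Derive a reproducible substream seed
#'
#' Fans one master seed out into independent substreams keyed by integer
#' tags (subject, scan, pipeline, ...), so adding subjects or scans never
#' perturbs the draws of existing ones. [dc_curve()] seeds the two tie-
#' breaking streams of subject `s` with `derive_seed(seed, s, 1L)` and
#' `derive_seed(seed, s, 2L)`; use the same derivation to threshold a
#' subject's networks consistently with its Dice curve. A small LCG hash
#' keeps every intermediate below 2^53 (exact in doubles) and the result in
#' `[1, 2^31 - 2]`, valid for `set.seed()`.
#'
#' @param master Integer master seed.
#' @param ... Integer tags identifying the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  for (tag in c(...)) {
    x <- (x * 69069 + as.numeric(tag) + 1) %% m
    x <- (x * 69069 + 12345) %% m
  }
  as.integer(x %% (m - 1)) + 1L
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# sample sd by column, two-pass (centered) so constant columns give an sd at
# rounding level rather than the ~1e-8 a one-pass formula can leave behind
col_sds <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  d <- x - rep(m, each = n)
  sqrt(colSums(d * d) / (n - 1))
}
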