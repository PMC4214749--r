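#' Read a weighted connectivity matrix
#'
#' Reads a tab-separated square matrix whose header row and index column both
#' carry node labels. Rows/columns are permuted into scheme order; labels that
#' do not match the scheme are an error.
#'
#' @param path TSV path.
#' @param scheme A [parcellation_scheme()] defining the expected labels and
#'   canonical order.
#' @param tol Symmetry tolerance, see [weighted_network()].
#' @return A [weighted_network()].
#' @export
read_weight_matrix <- function(path, scheme, tol = 1e-9) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  W <- as.matrix(tab)
  if (nrow(W) != ncol(W))
    stopf("matrix in %s is not square (%d x %d)", path, nrow(W), ncol(W))
  weighted_network(scheme, W, tol = tol)
}

#' Write a weighted connectivity matrix
#'
#' @param net A [weighted_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  df <- data.frame(label = rownames(net$W), net$W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Writes a binary network (or the intersection network of a consensus
#' result) as GraphML with node attributes `label`, `hemisphere`, `lobe` and,
#' when available, the per-edge `prevalence` across subjects.
#'
#' @param net A [binary_network()] or `consensus_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  prevalence <- NULL
  if (inherits(net, "consensus_result")) {
    prevalence <- net$prevalence
    net <- net$intersection
  }
  stopifnot(inherits(net, "binary_network"))
  sch <- net$scheme
  g <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
  igraph::V(g)$label <- sch$nodes$label
  igraph::V(g)$hemisphere <- sch$nodes$hemisphere
  igraph::V(g)$lobe <- sch$nodes$lobe
  if (!is.null(prevalence) && igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$prevalence <- prevalence[cbind(ends[, 1], ends[, 2])]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read analysis results as JSON
#'
#' Serialises convergence curves and consensus summaries (plain lists of
#' numeric vectors) to JSON and back.
#'
#' @param x A list-like result object (e.g. a `convergence_curve`).
#' @param path JSON path.
#' @return For the writer, `path` invisibly; for the reader, the parsed list.
#' @export
write_result_json <- function(x, path) {
  cls <- class(x)
  out <- unclass(x)
  out[["_class"]] <- cls[1]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- out[["_class"]]
  out[["_class"]] <- NULL
  if (!is.null(cls)) class(out) <- c(cls, "list")
  out
}
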