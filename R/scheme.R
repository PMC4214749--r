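#' Parcellation schemes
#'
#' A parcellation scheme is the ordered list of cortical parcels (network
#' nodes) that defines the axis order of every connectivity matrix bound to
#' it. Each node carries a hemisphere (`"L"` or `"R"`) and a lobe annotation.
#' Typical node scales for whole-cortex atlases are 34 (common/merged scale),
#' 44 (Hammers), 68 (Desikan-Killiany) and 78 (AAL).
#'
#' @param name Scheme name (e.g. `"dk68"`).
#' @param labels Character vector of unique node labels, in canonical order.
#' @param hemisphere Character vector, one of `"L"`/`"R"` per node.
#' @param lobe Character vector, one of the six lobe categories per node:
#'   `"temporal"`, `"frontal"`, `"parietal"`, `"occipital"`, `"insula"`,
#'   `"limbic/cingulate"`.
#' @return An object of class `parcellation_scheme`: a list with elements
#'   `name`, `nodes` (data frame with columns `label`, `hemisphere`, `lobe`)
#'   and `N` (node count).
#' @examples
#' sch <- parcellation_scheme("toy",
#'   labels = c("lh_a", "lh_b", "rh_a", "rh_b"),
#'   hemisphere = c("L", "L", "R", "R"),
#'   lobe = rep("frontal", 4))
#' sch$N
#' @export
parcellation_scheme <- function(name, labels, hemisphere, lobe) {
  labels <- as.character(labels)
  hemisphere <- as.character(hemisphere)
  lobe <- as.character(lobe)
  if (length(labels) < 2L)
    stopf("a parcellation scheme needs at least 2 nodes, got %d", length(labels))
  if (anyDuplicated(labels))
    stopf("duplicate node labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(hemisphere) != length(labels) || length(lobe) != length(labels))
    stopf("labels, hemisphere and lobe must have equal length")
  if (!all(hemisphere %in% c("L", "R")))
    stopf("hemisphere must be 'L' or 'R' for every node")
  lobes_ok <- c("temporal", "frontal", "parietal", "occipital", "insula",
                "limbic/cingulate")
  if (!all(lobe %in% lobes_ok))
    stopf("unknown lobe value(s): %s",
          paste(setdiff(unique(lobe), lobes_ok), collapse = ", "))
  structure(
    list(name = as.character(name)[1],
         nodes = data.frame(label = labels, hemisphere = hemisphere,
                            lobe = lobe, stringsAsFactors = FALSE),
         N = length(labels)),
    class = "parcellation_scheme")
}

#' @export
print.parcellation_scheme <- function(x, ...) {
  cat(sprintf("<parcellation_scheme '%s': %d nodes (%d L / %d R)>\n",
              x$name, x$N, sum(x$nodes$hemisphere == "L"),
              sum(x$nodes$hemisphere == "R")))
  invisible(x)
}

#' Read a parcellation label table
#'
#' Reads a tab-separated table with columns `label`, `hemisphere`, `lobe`
#' (header required). Row order in the file is the canonical node order.
#'
#' @param path Path to a TSV file.
#' @param name Scheme name; defaults to the file name without extension.
#' @return A [parcellation_scheme()].
#' @export
read_scheme <- function(path, name = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "lobe")
  if (!all(need %in% names(tab)))
    stopf("scheme table %s must have columns: %s", path,
          paste(need, collapse = ", "))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  parcellation_scheme(name, tab$label, tab$hemisphere, tab$lobe)
}

#' Write a parcellation label table
#'
#' @param scheme A [parcellation_scheme()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  utils::write.table(scheme$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Atlas correspondence (merge) tables
#'
#' A correspondence table maps every parcel label of a source scheme onto a
#' parcel of a coarser target scheme, e.g. Desikan-Killiany (68 nodes) onto
#' the common 34-node scale. The mapping must cover all source labels and is
#' expected to be identical in the two hemispheres.
#'
#' @param source Character vector of source labels.
#' @param target Character vector of target labels, same length.
#' @param source_scheme,target_scheme Optional scheme names (metadata).
#' @param hemi_asymmetry How to react if the left- and right-hemisphere halves
#'   of the mapping differ (labels are matched across hemispheres by stripping
#'   a leading `lh_`/`rh_` or trailing `_L`/`_R` marker): `"warn"` (default)
#'   or `"error"`. Tables whose labels carry no hemisphere marker are not
#'   checked.
#' @return An object of class `correspondence_table` with elements
#'   `source_scheme`, `target_scheme`, `mapping` (named character vector,
#'   names = source labels).
#' @export
correspondence_table <- function(source, target, source_scheme = NA_character_,
                                 target_scheme = NA_character_,
                                 hemi_asymmetry = c("warn", "error")) {
  hemi_asymmetry <- match.arg(hemi_asymmetry)
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target))
    stopf("source and target must have equal length")
  if (anyDuplicated(source))
    stopf("duplicate source labels: %s",
          paste(unique(source[duplicated(source)]), collapse = ", "))
  mapping <- stats::setNames(target, source)
  check_hemisphere_symmetry(mapping, hemi_asymmetry)
  structure(
    list(source_scheme = source_scheme, target_scheme = target_scheme,
         mapping = mapping),
    class = "correspondence_table")
}

# Strip hemisphere markers so L/R variants of a parcel share a stem.
strip_hemi <- function(x) {
  x <- sub("^(lh|rh)[_.]", "", x)
  sub("[_.](L|R)$", "", x)
}

check_hemisphere_symmetry <- function(mapping, action) {
  src <- names(mapping)
  is_l <- grepl("^lh[_.]", src) | grepl("[_.]L$", src)
  is_r <- grepl("^rh[_.]", src) | grepl("[_.]R$", src)
  if (!any(is_l) || !any(is_r)) return(invisible(TRUE))
  lmap <- stats::setNames(strip_hemi(unname(mapping[is_l])), strip_hemi(src[is_l]))
  rmap <- stats::setNames(strip_hemi(unname(mapping[is_r])), strip_hemi(src[is_r]))
  shared <- intersect(names(lmap), names(rmap))
  bad <- shared[lmap[shared] != rmap[shared]]
  if (length(bad)) {
    msg <- sprintf("correspondence table is not hemisphere-symmetric for: %s",
                   paste(bad, collapse = ", "))
    if (action == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  invisible(TRUE)
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("<correspondence_table: %d source labels -> %d target labels>\n",
              length(x$mapping), length(unique(x$mapping))))
  invisible(x)
}

#' Read a correspondence table
#'
#' Two-column TSV (header `source`, `target`, or headerless two columns).
#'
#' @inheritParams correspondence_table
#' @param path Path to the TSV file.
#' @return A [correspondence_table()].
#' @export
read_correspondence <- function(path, hemi_asymmetry = c("warn", "error")) {
  hemi_asymmetry <- match.arg(hemi_asymmetry)
  head1 <- utils::read.delim(path, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  has_header <- identical(tolower(as.character(head1[1, 1:2])),
                          c("source", "target"))
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stopf("correspondence table %s must have two columns", path)
  correspondence_table(tab[[1]], tab[[2]], hemi_asymmetry = hemi_asymmetry)
}

#' Write a correspondence table
#' @param table A [correspondence_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correspondence <- function(table, path) {
  stopifnot(inherits(table, "correspondence_table"))
  utils::write.table(
    data.frame(source = names(table$mapping), target = unname(table$mapping)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Apply a correspondence table to a scheme: returns the merged target scheme
# plus the source->target index map. Target node order: by first appearance
# of each target among the source order (keeps hemisphere interleaving).
merged_scheme <- function(scheme, table) {
  stopifnot(inherits(scheme, "parcellation_scheme"),
            inherits(table, "correspondence_table"))
  src <- scheme$nodes$label
  missing <- setdiff(src, names(table$mapping))
  if (length(missing))
    stopf("correspondence table does not map scheme label(s): %s",
          paste(missing, collapse = ", "))
  tgt <- unname(table$mapping[src])
  tgt_labels <- unique(tgt)
  group <- match(tgt, tgt_labels)
  # annotation of a merged node: hemisphere/lobe of its first member
  first <- match(tgt_labels, tgt)
  out <- parcellation_scheme(
    name = if (!is.na(table$target_scheme)) table$target_scheme
           else paste0(scheme$name, "_merged"),
    labels = tgt_labels,
    hemisphere = scheme$nodes$hemisphere[first],
    lobe = scheme$nodes$lobe[first])
  list(scheme = out, group = group)
}
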