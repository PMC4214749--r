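test_that("weight matrices round-trip through TSV", {
  sch <- parcellation_scheme("abc", c("a", "b", "c"), c("L", "R", "L"),
                             rep("frontal", 3))
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 2.5
  net <- weighted_network(sch, W)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weight_matrix(net, path)
  back <- read_weight_matrix(path, sch)
  expect_equal(back$W[1, 2], 2.5)
  expect_equal(back$W[2, 1], 2.5)
  expect_identical(rownames(back$W), sch$nodes$label)

  # random 34-node matrix: labels bitwise equal, weights < 1e-12 off
  sch34 <- toy_scheme(34)
  net34 <- rand_weighted(sch34, 7)
  write_weight_matrix(net34, path)
  back34 <- read_weight_matrix(path, sch34)
  expect_identical(rownames(back34$W), rownames(net34$W))
  expect_lt(max(abs(back34$W - net34$W)), 1e-12)
})

test_that("matrix reader permutes file order into scheme order", {
  sch <- toy_scheme(4)
  net <- rand_weighted(sch, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  perm <- c(3, 1, 4, 2)
  Wp <- net$W[perm, perm]
  df <- data.frame(label = rownames(Wp), Wp, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_weight_matrix(path, sch)
  expect_equal(back$W, net$W)
})

test_that("invalid matrices are rejected with informative errors", {
  sch <- parcellation_scheme("ab", c("a", "b"), c("L", "R"), rep("insula", 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\ta\tb", "a\t0\t1", "b\t3\t0"), path)
  expect_error(read_weight_matrix(path, sch), "asymmetric")
  writeLines(c("label\ta\tb", "a\t0\t-1", "b\t-1\t0"), path)
  expect_error(read_weight_matrix(path, sch), "negative")
  writeLines(c("label\ta\tz", "a\t0\t1", "z\t1\t0"), path)
  expect_error(read_weight_matrix(path, sch), "z")
  # asymmetry within tolerance is symmetrised exactly
  W <- matrix(c(0, 1 + 1e-12, 1, 0), 2, 2)
  net <- weighted_network(sch, W)
  expect_identical(net$W, t(net$W))
})

test_that("scheme construction enforces its invariants", {
  expect_error(parcellation_scheme("x", c("a", "a"), c("L", "R"),
                                   rep("frontal", 2)), "duplicate")
  expect_error(parcellation_scheme("x", "a", "L", "frontal"), "at least 2")
  expect_error(parcellation_scheme("x", c("a", "b"), c("L", "M"),
                                   rep("frontal", 2)), "hemisphere")
  expect_error(parcellation_scheme("x", c("a", "b"), c("L", "R"),
                                   c("frontal", "elbow")), "lobe")
})

test_that("correspondence tables check surjectivity and hemisphere symmetry", {
  # worked merge example: the three inferior-frontal subdivisions
  tab <- correspondence_table(
    c("lh_parsopercularis", "lh_parsorbitalis", "lh_parstriangularis",
      "rh_parsopercularis", "rh_parsorbitalis", "rh_parstriangularis"),
    c(rep("lh_inferior_frontal_gyrus", 3), rep("rh_inferior_frontal_gyrus", 3)))
  expect_s3_class(tab, "correspondence_table")
  expect_length(unique(tab$mapping), 2)

  # identity mapping: target count = source count
  sch <- toy_scheme(6)
  id <- correspondence_table(sch$nodes$label, sch$nodes$label)
  expect_length(unique(id$mapping), sch$N)

  # asymmetric mapping warns by default, errors on request
  expect_warning(
    correspondence_table(c("lh_a", "rh_a"), c("lh_x", "rh_y")),
    "hemisphere-symmetric")
  expect_error(
    correspondence_table(c("lh_a", "rh_a"), c("lh_x", "rh_y"),
                         hemi_asymmetry = "error"),
    "hemisphere-symmetric")
})

test_that("packaged DK->common table merges 68 labels into 34 (17 per hemisphere)", {
  sch68 <- read_scheme(extdata("scheme_dk68.tsv"))
  expect_equal(sch68$N, 68)
  tab <- read_correspondence(extdata("corr_dk68_to_common34.tsv"))
  expect_length(unique(tab$mapping), 34)
  m <- merged_scheme(sch68, tab)$scheme
  expect_equal(m$N, 34)
  expect_equal(sum(m$nodes$hemisphere == "L"), 17)
  expect_equal(sum(m$nodes$hemisphere == "R"), 17)
  # unmapped source label when applied to a scheme is an error
  tab2 <- correspondence_table("lh_bankssts", "lh_temporal_lobe")
  expect_error(merged_scheme(sch68, tab2), "does not map")
})

test_that("GraphML export carries attributes and round-trips edge sets", {
  sch <- toy_scheme(4)
  path <- withr::local_tempfile(fileext = ".graphml")

  empty <- binary_network(sch, matrix(0L, 4, 4))
  write_graphml(empty, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 0)

  k4 <- binary_network(sch, matrix(1L, 4, 4) - diag(1L, 4))
  write_graphml(k4, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), 6)
  expect_setequal(igraph::V(g)$hemisphere, c("L", "R"))

  net <- rand_binary(toy_scheme(8), 0.4, 3)
  write_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  A_back <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(unname(A_back), unname(net$A * 1))
})

test_that("result JSON round-trips curve objects", {
  x <- structure(list(k = 1:3, densities = (1:3) / 3,
                      neglogp = c(0.5, 2, 1)),
                 class = "convergence_curve")
  path <- withr::local_tempfile(fileext = ".json")
  write_result_json(x, path)
  back <- read_result_json(path)
  expect_s3_class(back, "convergence_curve")
  expect_equal(back$neglogp, x$neglogp)
})
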