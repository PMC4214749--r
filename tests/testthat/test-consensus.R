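test_that("consensus prevalence counts within-subject pipeline agreement", {
  sch <- toy_scheme(4)
  # edge in both pipelines for all subjects -> prevalence 1
  a <- bn_from_pairs(sch, list(c(1, 2), c(1, 3)))
  res <- consensus_edges(list(a, a, a), list(a, a, a), metrics = FALSE)
  expect_equal(res$prevalence[1, 2], 1)
  expect_equal(res$intersection$k, 2L)

  # edge present in pipeline 1 only never becomes convergent
  b <- bn_from_pairs(sch, list(c(1, 4), c(3, 4)))
  res2 <- consensus_edges(list(a, a), list(b, b), metrics = FALSE)
  expect_true(all(res2$prevalence == 0))
  expect_equal(res2$intersection$k, 0L)

  # mixed two-subject example
  s1p1 <- bn_from_pairs(sch, list(c(1, 2), c(1, 3)))
  s1p2 <- bn_from_pairs(sch, list(c(1, 2), c(1, 3)))
  s2p1 <- bn_from_pairs(sch, list(c(1, 2), c(2, 4)))
  s2p2 <- bn_from_pairs(sch, list(c(1, 2), c(2, 4)))
  res3 <- consensus_edges(list(s1p1, s2p1), list(s1p2, s2p2), metrics = FALSE)
  expect_equal(res3$prevalence[1, 2], 1.0)
  expect_equal(res3$prevalence[1, 3], 0.5)
  expect_equal(res3$prevalence[2, 4], 0.5)
  expect_equal(edge_indices(res3$intersection), 1L + 4L * (2L - 1L))

  expect_error(consensus_edges(list(a), list(bn_from_pairs(sch, list(c(1, 2))))),
               "peak edge count")
})

test_that("intersection edges have prevalence exactly one", {
  sch <- toy_scheme(8)
  for (r in 1:5) {
    nets1 <- lapply(1:4, function(s)
      threshold_by_rank(rand_weighted(sch, 100 * r + s), 10, seed = s))
    nets2 <- lapply(1:4, function(s)
      threshold_by_rank(rand_weighted(sch, 200 * r + s), 10, seed = s))
    res <- consensus_edges(nets1, nets2, metrics = FALSE)
    inter_idx <- edge_indices(res$intersection)
    if (length(inter_idx)) expect_true(all(res$prevalence[inter_idx] == 1))
    expect_identical(res$prevalence, t(res$prevalence))
    expect_true(all(diag(res$prevalence) == 0))
    # every convergent subject set contains the intersection
    for (sc in res$subject_convergent)
      expect_true(all(sc$A >= res$intersection$A))
  }
})

test_that("graph metrics reproduce closed forms on canonical graphs", {
  sch4 <- toy_scheme(4)
  k4 <- binary_network(sch4, matrix(1L, 4, 4) - diag(1L, 4))
  expect_equal(as.numeric(characteristic_pathlength(k4)), 1.0)
  expect_equal(clustering_coefficient(k4), 1.0)
  expect_equal(global_efficiency(k4), 1.0)
  expect_equal(local_efficiency(k4), 1.0)

  sch5 <- toy_scheme(5)
  c5 <- bn_from_pairs(sch5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)))
  expect_equal(as.numeric(characteristic_pathlength(c5)), 1.5)
  expect_equal(global_efficiency(c5), mean(c(1, 1, 0.5, 0.5)))
  expect_warning(as_c5 <- assortativity(c5), "zero variance") # 2-regular
  expect_true(is.nan(as_c5))

  star <- bn_from_pairs(sch4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(assortativity(star), -1)

  # two disjoint K2 components: finite pairs all at distance 1
  k2k2 <- bn_from_pairs(sch4, list(c(1, 2), c(3, 4)))
  pl <- characteristic_pathlength(k2k2)
  expect_equal(as.numeric(pl), 1.0)
  expect_equal(attr(pl, "unreachable_pairs"), 8)

  empty <- bn_from_pairs(sch4, list())
  expect_equal(global_efficiency(empty), 0)
  expect_warning(pl0 <- characteristic_pathlength(empty), "undefined")
  expect_true(is.nan(as.numeric(pl0)))
  expect_error(assortativity(empty), "at least one edge")
})

test_that("all five metrics match brute-force oracles on random graphs", {
  set.seed(2718)
  for (r in 1:100) {
    n <- sample(5:15, 1)
    sch <- toy_scheme(n)
    net <- rand_binary(sch, runif(1, 0.2, 0.7), seed = 3000 + r)
    if (net$k == 0L) next
    A <- unname(net$A)
    expect_equal(as.numeric(characteristic_pathlength(net)),
                 oracle_pathlength(A), tolerance = 1e-12)
    expect_equal(clustering_coefficient(net), oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), oracle_geff(A), tolerance = 1e-12)
    expect_equal(local_efficiency(net), oracle_leff(A), tolerance = 1e-12)
    as_pkg <- suppressWarnings(assortativity(net))
    as_orc <- oracle_assortativity(A)
    if (is.nan(as_orc)) expect_true(is.nan(as_pkg))
    else expect_equal(as_pkg, as_orc, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  sch <- toy_scheme(10)
  net <- rand_binary(sch, 0.4, seed = 55)
  set.seed(56)
  perm <- sample(10)
  net_p <- binary_network(sch, net$A[perm, perm])
  expect_equal(as.numeric(characteristic_pathlength(net_p)),
               as.numeric(characteristic_pathlength(net)))
  expect_equal(clustering_coefficient(net_p), clustering_coefficient(net))
  expect_equal(global_efficiency(net_p), global_efficiency(net))
  expect_equal(local_efficiency(net_p), local_efficiency(net))
  expect_equal(suppressWarnings(assortativity(net_p)),
               suppressWarnings(assortativity(net)))
})

test_that("the metrics table aggregates per-pipeline means and sds", {
  sch <- toy_scheme(8)
  net <- threshold_by_rank(rand_weighted(sch, 3), 10, seed = 1)
  # single subject: sd column is all zero
  single <- metrics_table(list(net), list(net))
  expect_true(all(single$summary$sd == 0))
  # identical subjects: sd 0 and means equal the single-network metrics
  trip <- metrics_table(list(net, net, net), list(net, net, net))
  expect_true(all(trip$summary$sd == 0, na.rm = TRUE))
  m <- network_metrics(net)
  expect_equal(trip$summary$mean[trip$summary$pipeline == "P1"],
               unlist(m[c("PL", "CC", "Geff", "Leff", "AS")]),
               ignore_attr = TRUE)
  # heterogeneous subjects: means equal the mean of per-network oracle values
  nets1 <- lapply(1:5, function(s) threshold_by_rank(rand_weighted(sch, s), 10, s))
  nets2 <- lapply(1:5, function(s) threshold_by_rank(rand_weighted(sch, 50 + s), 10, s))
  tab <- metrics_table(nets1, nets2)
  cc_mean <- mean(vapply(nets1, function(b) oracle_clustering(unname(b$A)),
                         numeric(1)))
  expect_equal(tab$summary$mean[tab$summary$pipeline == "P1" &
                                  tab$summary$metric == "CC"], cc_mean)
})
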