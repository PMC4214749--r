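test_that("fiber density weights follow count / mean boundary volume", {
  sch <- parcellation_scheme("ab3", c("A", "B", "C"), c("L", "R", "L"),
                             rep("parietal", 3))
  vols <- c(A = 2, B = 4, C = 1)
  rec <- data.frame(fiber_id = 1:10, parcel_a = "A", parcel_b = "B")
  net <- build_weighted_network(fiber_endpoints(rec, vols), sch)
  expect_equal(net$W["A", "B"], 10 / 3) # 10 fibers / ((2 + 4) / 2)
  expect_equal(net$W["B", "A"], 10 / 3)
  expect_equal(net$W["A", "C"], 0)

  # fibers with both end-points in one parcel are discarded
  rec2 <- data.frame(fiber_id = 1:5, parcel_a = "A", parcel_b = "A")
  net2 <- build_weighted_network(fiber_endpoints(rec2, vols), sch)
  expect_true(all(net2$W == 0))
  expect_equal(attr(net2, "construction")$discarded_intra, 5)
})

test_that("construction matches the pair-tally oracle on random records", {
  sch <- toy_scheme(10)
  labels <- sch$nodes$label
  set.seed(11)
  vols <- stats::setNames(runif(10, 1, 5), labels)
  rec <- data.frame(fiber_id = seq_len(1000),
                    parcel_a = sample(labels, 1000, replace = TRUE),
                    parcel_b = sample(labels, 1000, replace = TRUE))
  net <- build_weighted_network(fiber_endpoints(rec, vols), sch)
  expect_equal(max(abs(net$W - oracle_build(rec, vols, labels))), 0,
               tolerance = 1e-12)
})

test_that("unknown labels error unless permissive, volumes must be positive", {
  sch <- parcellation_scheme("ab", c("A", "B"), c("L", "R"), rep("insula", 2))
  vols <- c(A = 1, B = 1)
  rec <- data.frame(fiber_id = 1:2, parcel_a = c("A", "A"),
                    parcel_b = c("B", "Z"))
  expect_error(build_weighted_network(fiber_endpoints(rec, vols), sch), "Z")
  net <- build_weighted_network(fiber_endpoints(rec, vols), sch,
                                permissive = TRUE)
  expect_equal(attr(net, "construction")$discarded_unknown, 1)
  expect_equal(net$W["A", "B"], 1)
  expect_error(fiber_endpoints(rec, c(A = 1, B = 0)), "positive")
  expect_error(build_weighted_network(fiber_endpoints(rec, c(A = 1, Z = 1)),
                                      sch), "volume")
})

test_that("scan averaging is the elementwise mean", {
  sch <- toy_scheme(6)
  net <- rand_weighted(sch, 5)
  expect_equal(average_scans(list(net))$W, net$W)
  expect_equal(average_scans(list(net, net, net))$W, net$W)
  net3 <- weighted_network(sch, 3 * net$W)
  expect_equal(average_scans(list(net, net3))$W, 2 * net$W)
  other <- rand_weighted(toy_scheme(7), 5)
  expect_error(average_scans(list(net, other)), "scheme")
})

test_that("node merging pools counts and volumes then re-applies the formula", {
  sch <- parcellation_scheme("m4", c("a1", "a2", "b", "c"),
                             c("L", "L", "R", "R"), rep("temporal", 4))
  vols <- c(a1 = 2, a2 = 2, b = 2, c = 2)
  rec <- data.frame(fiber_id = 1:5,
                    parcel_a = c("a1", "a1", "a2", "a2", "a2"),
                    parcel_b = c("b", "b", "b", "b", "b"))
  net <- build_weighted_network(fiber_endpoints(rec, vols), sch)
  tab <- correspondence_table(c("a1", "a2", "b", "c"), c("A", "A", "b", "c"))
  merged <- merge_nodes(net, tab, volumes = vols)
  # C(A,b) = 2 + 3 = 5, V(A) = 4, V(b) = 2 -> 5 / ((4 + 2) / 2) = 5/3
  expect_equal(merged$W["A", "b"], 5 / 3)
  expect_equal(merged$scheme$N, 3)

  # identity table leaves the network unchanged
  id <- correspondence_table(sch$nodes$label, sch$nodes$label)
  expect_equal(merge_nodes(net, id, volumes = vols)$W, unname(net$W),
               ignore_attr = TRUE)
})

test_that("count-mode merging commutes with construction on pre-merged endpoints", {
  sch <- toy_scheme(8)
  labels <- sch$nodes$label
  set.seed(21)
  vols <- stats::setNames(runif(8, 0.5, 3), labels)
  rec <- data.frame(fiber_id = seq_len(500),
                    parcel_a = sample(labels, 500, replace = TRUE),
                    parcel_b = sample(labels, 500, replace = TRUE))
  targets <- c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4")
  tab <- correspondence_table(labels, targets)

  net <- build_weighted_network(fiber_endpoints(rec, vols), sch)
  merged <- merge_nodes(net, tab, volumes = vols)

  # oracle route: merge endpoint labels first, then build
  map <- stats::setNames(targets, labels)
  rec2 <- data.frame(fiber_id = rec$fiber_id,
                     parcel_a = unname(map[rec$parcel_a]),
                     parcel_b = unname(map[rec$parcel_b]))
  vols2 <- tapply(vols, map[names(vols)], sum)
  sch2 <- parcellation_scheme("merged", unique(targets),
                              c("L", "R", "L", "R"), rep("frontal", 4))
  direct <- build_weighted_network(
    fiber_endpoints(rec2, stats::setNames(as.numeric(vols2), names(vols2))),
    sch2)
  expect_equal(max(abs(merged$W[rownames(direct$W), colnames(direct$W)] -
                         direct$W)), 0, tolerance = 1e-12)

  # fiber count is conserved up to the reported intra-group discard
  C_total <- sum(net$W * (outer(vols, vols, "+") / 2)) / 2
  Vm <- attr(merged, "merge")$merged_volumes
  C_merged <- sum(merged$W * (outer(Vm, Vm, "+") / 2)) / 2
  expect_equal(C_total,
               C_merged + attr(merged, "merge")$discarded_intra_group,
               tolerance = 1e-9)
})

test_that("weight-sum merge mode works without volumes and DK68 merges to 34 nodes", {
  sch68 <- read_scheme(extdata("scheme_dk68.tsv"))
  tab <- read_correspondence(extdata("corr_dk68_to_common34.tsv"))
  net <- rand_weighted(sch68, 13)
  merged <- merge_nodes(net, tab)
  expect_equal(merged$scheme$N, 34)
  expect_equal(attr(merged, "merge")$mode, "weight-sum")
  # off-group weights are plain sums
  g <- merged_scheme(sch68, tab)$group
  i_members <- which(g == 1)
  j_members <- which(g == 2)
  expect_equal(merged$W[1, 2], sum(net$W[i_members, j_members]))
})
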