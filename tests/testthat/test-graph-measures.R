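test_that("composition measures match hand counts on toy graphs", {
  tri <- sym_graph(3, list(c(1, 2), c(2, 3), c(1, 3)))
  cm <- composition_measures(tri)
  expect_equal(cm$density, 1)
  expect_equal(cm$degree, rep(2, 3), ignore_attr = TRUE)
  expect_equal(cm$strength, rep(2, 3), ignore_attr = TRUE)
  expect_equal(cm$largest_cluster_size, 3)
  two_edges <- sym_graph(4, list(c(1, 2), c(3, 4)))
  cm2 <- composition_measures(two_edges)
  expect_equal(cm2$density, 1 / 3)
  expect_equal(cm2$largest_cluster_size, 2)
})

test_that("distance measures match hand-enumerable cases", {
  cyc4 <- sym_graph(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  dm <- distance_measures(cyc4)
  expect_equal(dm$characteristic_path_length, 4 / 3)
  expect_equal(dm$global_efficiency, 5 / 6)
  expect_equal(dm$radius, 2)
  expect_equal(dm$diameter, 2)
  path3 <- sym_graph(3, list(c(1, 2), c(2, 3)))
  dm3 <- distance_measures(path3)
  expect_equal(dm3$radius, 1)
  expect_equal(dm3$diameter, 2)
  expect_error(distance_measures(matrix(0, 3, 3)), "degenerate-input")
})

test_that("betweenness matches path-position intuition and stars", {
  path3 <- sym_graph(3, list(c(1, 2), c(2, 3)))
  expect_equal(betweenness_centrality(path3), c(0, 1, 0))
  star5 <- sym_graph(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(betweenness_centrality(star5), c(6, 0, 0, 0, 0))
})

test_that("eigenvector centrality is symmetric, scaled and scale-invariant", {
  tri <- sym_graph(3, list(c(1, 2), c(2, 3), c(1, 3)))
  v <- eigenvector_centrality(tri)
  expect_equal(v, rep(1 / sqrt(3), 3))
  path3 <- sym_graph(3, list(c(1, 2), c(2, 3)))
  v3 <- eigenvector_centrality(path3)
  expect_equal(v3[2], sqrt(2) * v3[1], tolerance = 1e-10)
  expect_equal(eigenvector_centrality(path3 * 7.5), v3, tolerance = 1e-10)
  expect_equal(sum(v3^2), 1)
})

test_that("clustering suite matches triangle geometry", {
  tri <- sym_graph(3, list(c(1, 2), c(2, 3), c(1, 3)))
  cl <- clustering_measures(tri)
  expect_equal(cl$clustering, rep(1, 3))
  expect_equal(cl$transitivity, 1)
  expect_equal(cl$local_efficiency, rep(1, 3))
  path3 <- sym_graph(3, list(c(1, 2), c(2, 3)))
  expect_equal(clustering_measures(path3)$clustering, rep(0, 3))
  trip <- sym_graph(4, list(c(1, 2), c(2, 3), c(1, 3), c(1, 4)))
  expect_equal(clustering_measures(trip)$clustering[1], 1 / 3)
})

test_that("community detection resolves two disjoint triangles with Q = 0.5", {
  two_tri <- sym_graph(6, list(c(1, 2), c(2, 3), c(1, 3),
                               c(4, 5), c(5, 6), c(4, 6)))
  com <- community_measures(two_tri, seed = 5)
  expect_equal(com$q, 0.5)
  expect_equal(length(unique(com$partition)), 2)
  expect_equal(com$partition[1:3], rep(com$partition[1], 3))
  # all edges within own module: participation 0
  expect_equal(com$participation, rep(0, 6))
  # exhaustive-partition oracle agrees
  expect_equal(com$q, oracle_max_modularity(two_tri), tolerance = 1e-10)
})

test_that("participation reflects cross-module strength splits", {
  # node 5 splits strength equally across two modules -> P = 0.5
  W <- sym_graph(5, list(c(1, 2), c(3, 4), c(5, 1), c(5, 3)))
  part <- c(1, 1, 2, 2, 3)
  p <- participation_coefficient(W, part)
  expect_equal(p[5], 0.5)
})

test_that("assortativity matches endpoint-degree correlation", {
  path3 <- sym_graph(3, list(c(1, 2), c(2, 3)))
  expect_equal(assortativity_weighted(path3), -1)
  ring <- sym_graph(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)))
  expect_warning(expect_true(is.na(assortativity_weighted(ring))),
                 "undefined-result")
  for (s in 1:5) {
    W <- random_connected_weighted(7, seed = s)
    expect_equal(assortativity_weighted(W), oracle_assortativity(W),
                 tolerance = 1e-10)
  }
})

test_that("every measure equals its brute-force oracle on random weighted graphs", {
  for (s in 1:8) {
    n <- sample(5:7, 1)
    W <- random_connected_weighted(n, p = 0.6, seed = 100 + s)
    expect_equal(distance_measures(W)$characteristic_path_length,
                 oracle_charpath(W), tolerance = 1e-10)
    expect_equal(distance_measures(W)$global_efficiency,
                 oracle_global_efficiency(W), tolerance = 1e-10)
    rd <- oracle_radius_diameter(W)
    expect_equal(distance_measures(W)$radius, unname(rd["radius"]),
                 tolerance = 1e-10)
    expect_equal(distance_measures(W)$diameter, unname(rd["diameter"]),
                 tolerance = 1e-10)
    expect_equal(betweenness_centrality(W), oracle_betweenness(W),
                 tolerance = 1e-8)
    cl <- clustering_measures(W)
    expect_equal(cl$clustering, oracle_clustering(W), tolerance = 1e-10)
    expect_equal(cl$transitivity, oracle_transitivity(W), tolerance = 1e-10)
    expect_equal(cl$local_efficiency, oracle_local_efficiency(W),
                 tolerance = 1e-10)
    ev <- eigenvector_centrality(W)
    expect_equal(abs(ev), abs(oracle_eigenvector(W)), tolerance = 1e-6)
    cm <- composition_measures(W)
    A <- W > 0
    expect_equal(cm$degree, rowSums(A), ignore_attr = TRUE)
    expect_equal(cm$strength, rowSums(W), ignore_attr = TRUE)
  }
})

test_that("Louvain modularity never exceeds the exhaustive maximum", {
  for (s in 1:6) {
    n <- sample(6:8, 1)
    W <- random_connected_weighted(n, p = 0.4, seed = 200 + s)
    q <- community_measures(W, seed = s)$q
    expect_lte(q, oracle_max_modularity(W) + 1e-10)
  }
})

test_that("small-worldness exceeds 1 for a ring lattice and is seed-stable", {
  n <- 20
  edges <- c(lapply(1:n, function(i) c(i, i %% n + 1)),
             lapply(1:n, function(i) c(i, (i + 1) %% n + 1)))
  rl <- sym_graph(n, edges)
  s1 <- small_worldness(rl, n_null = 50, seed = 7)
  expect_gt(s1, 1)
  expect_identical(s1, small_worldness(rl, n_null = 50, seed = 7))
  expect_error(small_worldness(sym_graph(3, list(c(1, 2), c(2, 3)))),
               "invalid-argument")
})

test_that("small-worldness of a dense random graph is near 1", {
  set.seed(33)
  W <- random_connected_weighted(24, p = 0.5, seed = 33)
  s <- small_worldness(W, n_null = 30, seed = 9)
  expect_gt(s, 0.8)
  expect_lt(s, 1.25)
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  W <- random_connected_weighted(12, p = 0.4, seed = 77)
  Wn <- laminarnet:::rewire_preserving_degree(W, 10, 5)
  expect_equal(rowSums(Wn > 0), rowSums(W > 0))
  expect_equal(sort(Wn[upper.tri(Wn) & Wn > 0]),
               sort(W[upper.tri(W) & W > 0]))
})

test_that("trapezoidal AUC is exact on constants and linear curves", {
  g <- density_grid()
  expect_equal(auc_over_grid(rep(2, length(g)), g), 0.76)
  expect_equal(auc_over_grid(g, g), (0.40^2 - 0.02^2) / 2)
  a <- 1.7; b <- -3.2
  expect_equal(auc_over_grid(a + b * g, g),
               a * 0.38 + b * (0.40^2 - 0.02^2) / 2, tolerance = 1e-12)
  expect_error(auc_over_grid(1:3, g), "invalid-argument")
})

test_that("AUC is linear in its input curves", {
  g <- density_grid()
  set.seed(10)
  x <- rnorm(length(g)); y <- rnorm(length(g))
  expect_equal(auc_over_grid(2 * x + 3 * y, g),
               2 * auc_over_grid(x, g) + 3 * auc_over_grid(y, g),
               tolerance = 1e-12)
})

test_that("layer aggregation averages nodal values per depth", {
  channels <- data.frame(roi_id = rep(0:3, 2), depth = rep(1:2, each = 4))
  agg <- layer_aggregate(rep(1, 8), channels)
  expect_equal(agg$mean_value, c(1, 1))
  agg2 <- layer_aggregate(channels$depth, channels)
  expect_equal(agg2$mean_value, c(1, 2))
  set.seed(2)
  v <- rnorm(8)
  agg3 <- layer_aggregate(v, channels)
  expect_equal(agg3$mean_value,
               as.numeric(tapply(v, channels$depth, mean)))
  expect_equal(agg3$n_nodes, c(4L, 4L))
  expect_error(layer_aggregate(1:3, channels), "incompatible-input")
})

test_that("composition measures grow monotonically along the density grid", {
  W <- abs(random_sym(15, seed = 14))
  cm <- cm_single(W / max(W))
  prev <- NULL
  for (d in density_grid()) {
    thr <- threshold_proportional(cm, d)
    m <- composition_measures(thr)
    cur <- c(m$density, mean(m$degree), mean(m$strength),
             m$largest_cluster_size)
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("measure curves produce finite AUCs for the default suite", {
  ts <- tiny_participant(n_roi = 10, n_depths = 2, n_timepoints = 150)
  lbl <- build_layer_by_layer(ts)
  mc <- measure_curves(normalize_weights(lbl[[1]]), seed = 4)
  expect_equal(nrow(mc$global), length(default_global_measures()))
  # assortativity is undefined (NA) when a sparse grid point has < 2 edges
  # or zero endpoint-strength variance; everything else must be finite
  finite_required <- mc$global$measure != "assortativity"
  expect_true(all(is.finite(mc$global$auc[finite_required])))
  mc_nodal <- measure_curves(normalize_weights(lbl[[1]]),
                             global_measures = character(),
                             nodal_measures = c("degree", "strength"),
                             seed = 4)
  expect_equal(dim(mc_nodal$nodal$degree$values), c(10, 20))
  expect_length(mc_nodal$nodal$strength$auc, 10)
})
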