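test_that("Fisher z-transform clamps perfect correlations and matches arctanh", {
  tt <- 1:100
  x <- sin(tt / 5)
  ts <- laminar_ts("p", cbind(x, x, rnorm(100)),
                   data.frame(roi_id = 0:2, depth = rep(1L, 3)), 2.8)
  cm <- correlation_fisher(ts, pipeline_tag = "layer_by_layer")
  expect_equal(cm$weights[1, 2], atanh(1 - 1e-7))
  expect_true(all(is.finite(cm$weights)))
  # orthogonal sinusoids over whole periods: r ~ 0
  tt <- 0:199
  a <- sin(2 * pi * tt / 50)
  b <- cos(2 * pi * tt / 50)
  ts2 <- laminar_ts("p", cbind(a, b),
                    data.frame(roi_id = 0:1, depth = c(1L, 1L)), 2.8)
  expect_lt(abs(correlation_fisher(ts2)$weights[1, 2]), 1e-10)
})

test_that("Fisher z equals arctanh of the Pearson matrix", {
  set.seed(8)
  dat <- matrix(rnorm(80 * 5), 80, 5)
  ts <- laminar_ts("p", dat, data.frame(roi_id = 0:4, depth = rep(1L, 5)), 2.8)
  z <- correlation_fisher(ts)$weights
  ref <- atanh(cor(dat))
  diag(ref) <- 0
  expect_equal(z, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance channels are reported by name", {
  dat <- cbind(rnorm(50), rep(1, 50))
  ts <- laminar_ts("p", dat, data.frame(roi_id = 0:1, depth = c(1L, 1L)), 2.8)
  expect_error(correlation_fisher(ts), "roi001_depth1")
})

test_that("layer-by-layer and multilayer constructions have the stated pair counts", {
  ts <- tiny_participant(n_roi = 6, n_depths = 3, n_timepoints = 100)
  lbl <- build_layer_by_layer(ts)
  expect_length(lbl, 3)
  expect_equal(dim(lbl[[1]]$weights), c(6, 6))
  expect_equal(sum(upper.tri(lbl[[1]]$weights)), 6 * 5 / 2)
  ml <- build_multilayer(ts)
  expect_equal(dim(ml$weights), c(18, 18))
  expect_equal(sum(upper.tri(ml$weights)), 18 * 17 / 2)
  # R = 3: 3 unique pairs
  ts3 <- tiny_participant(n_roi = 4, n_depths = 2, n_timepoints = 60)
  expect_equal(sum(upper.tri(build_layer_by_layer(ts3)[[1]]$weights)), 6)
})

test_that("multilayer diagonal blocks equal the layer-by-layer matrices", {
  ts <- tiny_participant(n_roi = 8, n_depths = 3, n_timepoints = 120)
  ml <- build_multilayer(ts)
  lbl <- build_layer_by_layer(ts)
  for (d in 1:3) {
    idx <- which(ml$channels$depth == d)
    expect_equal(unname(ml$weights[idx, idx]), unname(lbl[[d]]$weights),
                 tolerance = 1e-12)
  }
})

test_that("weight normalization zeroes negatives and rescales to max 1", {
  W <- sym_graph(4, list(c(1, 2), c(2, 3), c(3, 4)), w = c(2, -1, 1))
  cm <- cm_single(W)
  norm <- normalize_weights(cm)
  expect_equal(norm$weights[2, 3], 0)
  expect_equal(max(norm$weights), 1)
  expect_equal(norm$weights[1, 2], 1)
  expect_equal(norm$weights[3, 4], 0.5)
  expect_true(all(norm$weights >= 0 & norm$weights <= 1))
  # idempotent when max is already 1
  expect_equal(normalize_weights(norm)$weights, norm$weights)
  # halves everything when max is 2
  W2 <- abs(random_sym(5, seed = 2)) * 2
  W2 <- W2 / max(W2) * 2
  expect_equal(normalize_weights(cm_single(W2))$weights, W2 / 2,
               ignore_attr = TRUE)
  expect_error(normalize_weights(cm_single(-abs(random_sym(4, 3)))),
               "degenerate-input")
})

test_that("proportional thresholding keeps the top-k positive weights", {
  # 6-edge toy: top 3 must survive at density 0.5
  W <- sym_graph(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
                 w = c(0.9, 0.2, 0.6, 0.4, 0.8, 0.1))
  thr <- threshold_proportional(cm_single(W), 0.5)
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 3)
  expect_equal(thr$weights[1, 2], 0.9)
  expect_equal(thr$weights[2, 4], 0.8)
  expect_equal(thr$weights[1, 4], 0.6)
  expect_equal(thr$weights[1, 3], 0)
  expect_equal(thr$density, 0.5)
  # density 1 on an all-positive matrix is the identity
  Wp <- abs(random_sym(6, seed = 4)) + 0.01
  diag(Wp) <- 0
  cmp <- cm_single(Wp / max(Wp))
  expect_equal(threshold_proportional(cmp, 1)$weights, cmp$weights)
})

test_that("realized density is within one edge of the request", {
  for (s in 1:100) {
    n <- sample(6:15, 1)
    W <- abs(random_sym(n, seed = s))
    cm <- cm_single(W / max(W))
    dens <- runif(1, 0.05, 0.9)
    thr <- threshold_proportional(cm, dens)
    npairs <- n * (n - 1) / 2
    expect_lte(abs(thr$density - dens) * npairs, 1)
  }
})

test_that("thresholded edge sets are nested along the density grid", {
  W <- abs(random_sym(12, seed = 9))
  cm <- cm_single(W / max(W))
  prev <- NULL
  for (d in density_grid()) {
    cur <- threshold_proportional(cm, d)$weights > 0
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("thresholding warns and keeps all positives when k exceeds supply", {
  W <- sym_graph(5, list(c(1, 2), c(2, 3)), w = c(0.5, 1))
  expect_warning(thr <- threshold_proportional(cm_single(W), 0.9),
                 "positive weights")
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 2)
  expect_equal(thr$density, 0.2)
})

test_that("within- and between-layer extraction partitions the supra matrix", {
  set.seed(21)
  n_roi <- 5; n_depths <- 3
  W <- abs(random_sym(n_roi * n_depths, seed = 21))
  ml <- cm_multi(W / max(W), n_roi, n_depths)
  thr <- threshold_proportional(ml, 0.3)
  within <- lapply(1:n_depths, function(d) extract_within_layer(thr, d))
  between <- extract_between_layer(thr)
  expect_equal(within[[1]]$pipeline_tag, "within_layer")
  expect_equal(between$pipeline_tag, "between_layer")
  # exact decomposition: embed within blocks + between = thresholded
  recon <- between$weights
  for (d in 1:n_depths) {
    idx <- which(thr$channels$depth == d)
    recon[idx, idx] <- recon[idx, idx] + within[[d]]$weights
  }
  expect_identical(recon, thr$weights)
  # edge counts: total = within + between
  cnt <- function(M) sum(M[upper.tri(M)] != 0)
  expect_equal(cnt(thr$weights),
               sum(vapply(within, function(w) cnt(w$weights), 0)) +
                 cnt(between$weights))
  expect_error(extract_within_layer(thr, 9), "invalid-argument")
  expect_error(extract_within_layer(within[[1]], 1), "invalid-argument")
})

test_that("between-layer extraction handles pure block structures", {
  n_roi <- 4; n_depths <- 2
  blockdiag <- matrix(0, 8, 8)
  blockdiag[1:4, 1:4] <- abs(random_sym(4, 1))
  blockdiag[5:8, 5:8] <- abs(random_sym(4, 2))
  ml <- cm_multi(blockdiag, n_roi, n_depths)
  expect_equal(max(abs(extract_between_layer(ml)$weights)), 0)
  offonly <- matrix(0.5, 8, 8)
  offonly[1:4, 1:4] <- 0
  offonly[5:8, 5:8] <- 0
  diag(offonly) <- 0
  ml2 <- cm_multi(offonly, n_roi, n_depths)
  expect_equal(extract_between_layer(ml2)$weights, ml2$weights)
  # empty within block
  w1 <- extract_within_layer(ml2, 1)
  expect_equal(max(abs(w1$weights)), 0)
  expect_equal(w1$density, 0)
})

test_that("connectivity matrices stay symmetric with zero diagonals", {
  ts <- tiny_participant(n_roi = 6, n_depths = 2, n_timepoints = 100)
  ml <- normalize_weights(build_multilayer(ts))
  for (d in c(0.1, 0.5)) {
    thr <- threshold_proportional(ml, d)
    expect_equal(thr$weights, t(thr$weights))
    expect_true(all(diag(thr$weights) == 0))
  }
})
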