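# Weighted graph-measure suite, Brain-Connectivity-Toolbox conventions:
# distances on 1/weight lengths, Onnela geometric-mean weighted clustering,
# neighborhood-subgraph local efficiency, strength assortativity,
# Louvain modularity with participation coefficient against its partition.

as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

dist_weights <- function(g) 1 / igraph::E(g)$weight

#' Composition measures
#'
#' Graph density (edges present over possible edges), nodal degree (count of
#' incident nonzero edges), nodal strength (sum of incident weights), and
#' the node count of the largest connected component.
#'
#' @param x a [connectivity_matrix()] or plain symmetric weight matrix.
#' @return List with `density`, `degree`, `strength`, `largest_cluster_size`.
#' @export
composition_measures <- function(x) {
  W <- as_weight_matrix(x)
  A <- (W != 0) * 1
  comp <- components_from_adjacency(A)
  list(density = realized_density(W),
       degree = rowSums(A),
       strength = rowSums(W),
       largest_cluster_size = max(tabulate(comp)))
}

components_from_adjacency <- function(A) {
  igraph::components(as_igraph(A))$membership
}

# all-pairs shortest path distances on 1/weight edge lengths
shortest_distances <- function(W) {
  g <- as_igraph(W)
  igraph::distances(g, weights = dist_weights(g))
}

#' Distance-based integration measures
#'
#' Shortest paths are computed on edge lengths `1/weight`. Characteristic
#' path length is the mean finite off-diagonal distance; global efficiency
#' the mean inverse distance (0 for disconnected pairs); radius and
#' diameter are the extreme eccentricities over the largest connected
#' component.
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @return List with `characteristic_path_length`, `global_efficiency`,
#'   `radius`, `diameter`.
#' @export
distance_measures <- function(x) {
  W <- as_weight_matrix(x)
  if (edge_count(W) == 0) stop_invalid("degenerate-input: edgeless graph")
  D <- shortest_distances(W)
  off <- upper.tri(D)
  finite <- off & is.finite(D)
  inv <- 1 / D[off]
  inv[!is.finite(inv)] <- 0
  comp <- components_from_adjacency((W != 0) * 1)
  main <- comp == which.max(tabulate(comp))
  ecc <- apply(D[main, main, drop = FALSE], 1L, max)
  list(characteristic_path_length = mean(D[finite]),
       global_efficiency = mean(inv),
       radius = min(ecc),
       diameter = max(ecc))
}

#' Betweenness centrality
#'
#' Fraction of shortest paths (on `1/weight` lengths) passing through each
#' node, endpoints excluded; path multiplicities are shared fractionally.
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @return Numeric vector, one value per node.
#' @export
betweenness_centrality <- function(x) {
  W <- as_weight_matrix(x)
  g <- as_igraph(W)
  if (igraph::ecount(g) == 0) return(rep(0, nrow(W)))
  unname(igraph::betweenness(g, weights = dist_weights(g), directed = FALSE))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, computed on the largest
#' connected component (zeros elsewhere), oriented nonnegative and scaled
#' to unit Euclidean norm.
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @return Numeric vector, one value per node.
#' @export
eigenvector_centrality <- function(x) {
  W <- as_weight_matrix(x)
  n <- nrow(W)
  comp <- components_from_adjacency((W != 0) * 1)
  main <- which(comp == which.max(tabulate(comp)))
  v <- rep(0, n)
  if (length(main) == 1L) {
    v[main] <- 1
    return(v)
  }
  e <- eigen(W[main, main], symmetric = TRUE)
  vec <- e$vectors[, 1L]
  if (sum(vec) < 0) vec <- -vec
  vec[vec < 0] <- 0
  v[main] <- vec / sqrt(sum(vec^2))
  v
}

#' Segregation measures: clustering, transitivity, local efficiency
#'
#' Weighted clustering uses the geometric mean of triangle weights
#' (intensity `(w_ij w_ih w_jh)^(1/3)`); transitivity is its closed-triple
#' generalization; local efficiency is the global efficiency of each node's
#' neighborhood subgraph. Weights are scaled by the maximum weight first
#' when any weight exceeds 1, so triangle intensities stay in \[0, 1\].
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @return List with `clustering` (per node), `transitivity`,
#'   `local_efficiency` (per node).
#' @export
clustering_measures <- function(x) {
  W <- as_weight_matrix(x)
  mx <- max(W)
  if (mx > 1) W <- W / mx
  k <- rowSums(W != 0)
  cw <- W^(1 / 3)
  tri <- diag(cw %*% cw %*% cw)  # 2x triangle intensity per node
  denom <- k * (k - 1)
  clustering <- ifelse(denom > 0, tri / denom, 0)
  transitivity <- if (sum(denom) > 0) sum(tri) / sum(denom) else 0
  leff <- neighborhood_efficiency(W)
  list(clustering = as.numeric(clustering), transitivity = transitivity,
       local_efficiency = leff)
}

#' Community structure and participation
#'
#' Louvain-style greedy modularity maximization at resolution `gamma`,
#' taking the best modularity over `n_restarts` seeded restarts with
#' permuted node orders. The participation coefficient
#' `P_i = 1 - sum_m (k_im / k_i)^2` is computed against the returned
#' partition using strengths.
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @param gamma resolution parameter.
#' @param n_restarts number of restarts.
#' @param seed integer seed for the restarts.
#' @return List with `partition` (integer memberships), `q` (modularity),
#'   `participation` (per node).
#' @export
community_measures <- function(x, gamma = 1, n_restarts = 10, seed = 1L) {
  W <- as_weight_matrix(x)
  if (edge_count(W) == 0) stop_invalid("degenerate-input: edgeless graph")
  g <- as_igraph(W)
  louvain_best(W, g, gamma, n_restarts, seed)
}

# Louvain's greedy pass is RNG-randomized; restarts are repeated seeded runs
# keeping the best-modularity partition.
louvain_best <- function(W, g, gamma, n_restarts, seed) {
  best_q <- -Inf
  best_memb <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      memb <- as.integer(igraph::membership(cl))
      q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                              resolution = gamma)
      if (q > best_q) {
        best_q <- q
        best_memb <- memb
      }
    }
  })
  list(partition = best_memb, q = best_q,
       participation = participation_coefficient(W, best_memb))
}

#' Participation coefficient against a given partition
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @param partition integer community memberships, one per node.
#' @return Numeric vector; 0 for isolated nodes.
#' @export
participation_coefficient <- function(x, partition) {
  W <- as_weight_matrix(x)
  k <- rowSums(W)
  mods <- sort(unique(partition))
  km2 <- rowSums(vapply(mods, function(m) {
    rowSums(W[, partition == m, drop = FALSE])^2
  }, numeric(nrow(W))))
  ifelse(k > 0, 1 - km2 / k^2, 0)
}

#' Strength (weighted-degree) assortativity
#'
#' Pearson correlation of endpoint strengths over edges, each undirected
#' edge contributing both orientations.
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) when endpoint
#'   strengths have zero variance.
#' @export
assortativity_weighted <- function(x) {
  W <- as_weight_matrix(x)
  pairs <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(pairs) < 2) stop_invalid("invalid-argument: need >= 2 edges")
  s <- rowSums(W)
  a <- c(s[pairs[, 1L]], s[pairs[, 2L]])
  b <- c(s[pairs[, 2L]], s[pairs[, 1L]])
  if (sd(a) == 0 || sd(b) == 0) {
    warning("undefined-result: zero variance of endpoint strengths")
    return(NA_real_)
  }
  cor(a, b)
}

#' Small-worldness sigma
#'
#' `sigma = (C / C_null) / (L / L_null)` on the largest connected component,
#' with `C` the mean weighted clustering coefficient and `L` the
#' characteristic path length; null statistics are means over `n_null`
#' degree-preserving randomizations (weighted double-edge swaps,
#' `swaps_per_edge` attempted swaps per edge).
#'
#' @param x a [connectivity_matrix()] or weight matrix.
#' @param n_null number of null networks.
#' @param seed integer seed.
#' @param swaps_per_edge attempted swaps per edge in each null.
#' @return Sigma (> 1 indicates small-world organization).
#' @export
small_worldness <- function(x, n_null = 100, seed = 1L, swaps_per_edge = 10) {
  W <- as_weight_matrix(x)
  comp <- components_from_adjacency((W != 0) * 1)
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < 4) {
    stop_invalid("invalid-argument: largest component must have >= 4 nodes")
  }
  W <- W[main, main, drop = FALSE]
  C <- mean(clustering_measures(W)$clustering)
  L <- distance_measures(W)$characteristic_path_length
  seeds <- derive_seeds(seed, n_null)
  nulls <- vapply(seeds, function(s) {
    Wn <- rewire_preserving_degree(W, swaps_per_edge, s)
    c(mean(clustering_measures(Wn)$clustering),
      distance_measures(Wn)$characteristic_path_length)
  }, numeric(2L))
  c_null <- mean(nulls[1L, ])
  l_null <- mean(nulls[2L, ])
  if (c_null <= 0 || l_null <= 0) {
    stop_invalid("numerical-failure: degenerate null statistics")
  }
  (C / c_null) / (L / l_null)
}

# Maslov-Sneppen double-edge swap keeping the binary degree sequence;
# weights travel with the first endpoint of each swapped edge.
rewire_preserving_degree <- function(W, swaps_per_edge, seed) {
  n <- nrow(W)
  pairs <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  ne <- nrow(pairs)
  if (ne < 2) return(W)
  edges <- pairs
  wts <- W[pairs]
  with_seed(seed, {
    attempts <- ceiling(swaps_per_edge * ne)
    A <- W != 0
    for (it in seq_len(attempts)) {
      ij <- sample.int(ne, 2L)
      e1 <- edges[ij[1L], ]
      e2 <- edges[ij[2L], ]
      a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
      if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (length(unique(c(a, b, c, d))) < 4L) next
      if (A[a, d] || A[c, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c, d] <- A[d, c] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c, b] <- A[b, c] <- TRUE
      edges[ij[1L], ] <- c(a, d)
      edges[ij[2L], ] <- c(c, b)
    }
  })
  Wn <- matrix(0, n, n)
  Wn[edges] <- wts
  Wn[edges[, 2:1, drop = FALSE]] <- wts
  Wn
}

#' Trapezoidal area under a measure curve
#'
#' @param values measure values, one per grid point.
#' @param grid density grid (fractions), same length as `values`.
#' @return The trapezoidal integral (measure units x density). `NA` values
#'   propagate.
#' @export
auc_over_grid <- function(values, grid = density_grid()) {
  if (length(values) != length(grid) || length(grid) < 2) {
    stop_invalid("invalid-argument: values and grid must have equal length >= 2")
  }
  if (anyNA(values)) return(NA_real_)
  pracma::trapz(grid, values)
}

#' Per-layer aggregation of a nodal measure
#'
#' @param values numeric vector aligned to `channels` rows.
#' @param channels `data.frame` with `roi_id` and `depth` per node.
#' @return `data.frame` with `layer`, `mean_value`, `n_nodes`.
#' @export
layer_aggregate <- function(values, channels) {
  if (length(values) != nrow(channels)) {
    stop_invalid("incompatible-input: %d values vs %d node labels",
                 length(values), nrow(channels))
  }
  agg <- tapply(values, channels$depth, mean)
  data.frame(layer = as.integer(names(agg)),
             mean_value = as.numeric(agg),
             n_nodes = as.integer(table(channels$depth)[names(agg)]))
}

#' Default measure sets
#'
#' The global suite covers composition (density, largest cluster size, mean
#' degree/strength), integration (characteristic path length, global
#' efficiency, radius, diameter, assortativity), centrality (mean
#' betweenness/eigenvector) and segregation (modularity, transitivity, mean
#' clustering, local efficiency, participation). Small-worldness is computed
#' separately via [small_worldness()] because of its null-model cost.
#'
#' @return Character vector of measure names.
#' @export
default_global_measures <- function() {
  c("density", "largest_cluster_size", "mean_degree", "mean_strength",
    "characteristic_path_length", "global_efficiency", "radius", "diameter",
    "assortativity", "mean_betweenness", "mean_eigenvector",
    "modularity", "transitivity", "mean_clustering", "mean_local_efficiency",
    "mean_participation")
}

#' @rdname default_global_measures
#' @export
default_nodal_measures <- function() {
  c("degree", "strength", "betweenness", "eigenvector", "clustering",
    "local_efficiency", "participation")
}

# measures on one thresholded matrix; returns list(global = named numeric,
# nodal = named list of vectors). Builds one igraph object shared by every
# measure. Distance/community measures are NA on an edgeless graph rather
# than an error, so curves over sparse grids stay rectangular.
measure_snapshot <- function(W, global_measures, nodal_measures,
                             gamma = 1, n_restarts = 10, seed = 1L) {
  W <- as_weight_matrix(W)
  need <- function(set, ...) any(c(...) %in% set)
  glob <- c()
  nodal <- list()
  n <- nrow(W)
  A <- (W != 0) * 1
  empty <- sum(A) == 0
  g <- as_igraph(W)
  dw <- if (!empty) 1 / igraph::E(g)$weight else numeric()
  comp <- igraph::components(g)$membership
  compm <- list(density = sum(A) / 2 / (n * (n - 1) / 2),
                degree = rowSums(A), strength = rowSums(W),
                largest_cluster_size = max(tabulate(comp)))
  if (need(global_measures, "characteristic_path_length", "global_efficiency",
           "radius", "diameter")) {
    dm <- if (empty) {
      list(characteristic_path_length = NA_real_, global_efficiency = NA_real_,
           radius = NA_real_, diameter = NA_real_)
    } else {
      D <- igraph::distances(g, weights = dw)
      off <- upper.tri(D)
      finite <- off & is.finite(D)
      inv <- 1 / D[off]
      inv[!is.finite(inv)] <- 0
      main <- comp == which.max(tabulate(comp))
      ecc <- apply(D[main, main, drop = FALSE], 1L, max)
      list(characteristic_path_length = mean(D[finite]),
           global_efficiency = mean(inv),
           radius = min(ecc), diameter = max(ecc))
    }
  }
  if (need(global_measures, "mean_betweenness") ||
      need(nodal_measures, "betweenness")) {
    btw <- if (empty) rep(0, n) else {
      unname(igraph::betweenness(g, weights = dw, directed = FALSE))
    }
  }
  if (need(global_measures, "mean_eigenvector") ||
      need(nodal_measures, "eigenvector")) {
    eig <- eigenvector_centrality(W)
  }
  if (need(global_measures, "transitivity", "mean_clustering",
           "mean_local_efficiency") ||
      need(nodal_measures, "clustering", "local_efficiency")) {
    clm <- clustering_measures(W)
  }
  if (need(global_measures, "modularity", "mean_participation") ||
      need(nodal_measures, "participation")) {
    com <- if (empty) {
      list(q = NA_real_, participation = rep(NA_real_, n))
    } else louvain_best(W, g, gamma, n_restarts, seed)
  }
  for (m in global_measures) {
    glob[m] <- switch(
      m,
      density = compm$density,
      largest_cluster_size = compm$largest_cluster_size,
      mean_degree = mean(compm$degree),
      mean_strength = mean(compm$strength),
      characteristic_path_length = dm$characteristic_path_length,
      global_efficiency = dm$global_efficiency,
      radius = dm$radius,
      diameter = dm$diameter,
      assortativity = tryCatch(
        suppressWarnings(assortativity_weighted(W)),
        error = function(e) NA_real_),
      mean_betweenness = mean(btw),
      mean_eigenvector = mean(eig),
      modularity = com$q,
      transitivity = clm$transitivity,
      mean_clustering = mean(clm$clustering),
      mean_local_efficiency = mean(clm$local_efficiency),
      mean_participation = mean(com$participation),
      stop_invalid("invalid-argument: unknown global measure '%s'", m)
    )
  }
  for (m in nodal_measures) {
    nodal[[m]] <- switch(
      m,
      degree = compm$degree,
      strength = compm$strength,
      betweenness = btw,
      eigenvector = eig,
      clustering = clm$clustering,
      local_efficiency = clm$local_efficiency,
      participation = com$participation,
      stop_invalid("invalid-argument: unknown nodal measure '%s'", m)
    )
  }
  list(global = glob, nodal = nodal)
}

#' Threshold-free measure curves with AUC
#'
#' Thresholds a normalized connectivity matrix at every density of the grid,
#' computes the requested graph measures at each density, and summarizes
#' each measure by its trapezoidal AUC over the grid.
#'
#' @param cm a normalized, unthresholded [connectivity_matrix()].
#' @param grid density grid, see [density_grid()].
#' @param global_measures,nodal_measures character vectors of measure names
#'   (see `laminarnet:::default_global_measures()`); either may be empty.
#' @param gamma,n_restarts,seed community-detection settings.
#' @return List with `global` (data.frame: measure x grid values + `auc`),
#'   `nodal` (per measure: node x grid matrix and `auc` vector), `grid`,
#'   and `realized_density`.
#' @export
measure_curves <- function(cm, grid = density_grid(),
                           global_measures = default_global_measures(),
                           nodal_measures = character(),
                           gamma = 1, n_restarts = 10, seed = 1L) {
  snaps <- lapply(grid, function(d) {
    thr <- threshold_proportional(cm, d)
    measure_snapshot(thr, global_measures, nodal_measures,
                     gamma, n_restarts, seed)
  })
  out <- list(grid = grid)
  if (length(global_measures)) {
    vals <- vapply(snaps, function(s) s$global[global_measures],
                   numeric(length(global_measures)))
    vals <- matrix(vals, nrow = length(global_measures),
                   dimnames = list(global_measures, NULL))
    out$global <- data.frame(
      measure = global_measures,
      vals,
      auc = apply(vals, 1L, auc_over_grid, grid = grid),
      check.names = FALSE, row.names = NULL
    )
    colnames(out$global)[2:(1 + length(grid))] <- sprintf("d%.2f", grid)
  }
  if (length(nodal_measures)) {
    out$nodal <- lapply(nodal_measures, function(m) {
      mat <- vapply(snaps, function(s) s$nodal[[m]],
                    numeric(nrow(cm$weights)))
      list(values = mat, auc = apply(mat, 1L, auc_over_grid, grid = grid))
    })
    names(out$nodal) <- nodal_measures
  }
  out
}
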