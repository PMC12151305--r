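# Brute-force reference implementations, independent of the package's
# computation paths (direct Floyd-Warshall, exhaustive path/partition
# enumeration, literal formula transcriptions). Used to verify every graph
# measure on small graphs.

sym_graph <- function(n, edges, w = 1) {
  W <- matrix(0, n, n)
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      wt <- if (length(w) > 1) w[k] else w
      W[i, j] <- W[j, i] <- wt
    }
  }
  W
}

oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_charpath <- function(W) {
  D <- oracle_distances(W)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracle_global_efficiency <- function(W) {
  D <- oracle_distances(W)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_components <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(W[v, ] > 0 & comp == 0L))
    }
  }
  comp
}

oracle_radius_diameter <- function(W) {
  comp <- oracle_components(W)
  main <- comp == which.max(tabulate(comp))
  D <- oracle_distances(W[main, main, drop = FALSE])
  ecc <- apply(D, 1, max)
  c(radius = min(ecc), diameter = max(ecc))
}

# all simple paths i -> j; returns list of node vectors
all_simple_paths_mat <- function(W, i, j) {
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == j) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in which(W[v, ] > 0)) {
      if (!visited[u]) {
        visited[u] <- TRUE
        walk(u, visited, c(path, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, nrow(W))
  visited[i] <- TRUE
  walk(i, visited, i)
  paths
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

# betweenness by exhaustive shortest-path enumeration (endpoints excluded)
oracle_betweenness <- function(W) {
  n <- nrow(W)
  btw <- rep(0, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- all_simple_paths_mat(W, i, j)
      if (!length(paths)) next
      lens <- vapply(paths, path_length, 0, W = W)
      mn <- min(lens)
      short <- paths[abs(lens - mn) < 1e-9]
      for (p in short) {
        inner <- setdiff(p, c(i, j))
        btw[inner] <- btw[inner] + 1 / length(short)
      }
    }
  }
  btw
}

# literal geometric-mean triangle formula
oracle_clustering <- function(W) {
  mx <- max(W)
  if (mx > 1) W <- W / mx
  n <- nrow(W)
  out <- rep(0, n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n))
      for (h in seq_len(n))
        if (j != i && h != i && j != h)
          s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_transitivity <- function(W) {
  mx <- max(W)
  if (mx > 1) W <- W / mx
  n <- nrow(W)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    den <- den + k * (k - 1)
    for (j in seq_len(n))
      for (h in seq_len(n))
        if (j != i && h != i && j != h)
          num <- num + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
  }
  if (den == 0) 0 else num / den
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(W[nb, nb, drop = FALSE])
  }, 0)
}

oracle_eigenvector <- function(W, iters = 2000) {
  comp <- oracle_components(W)
  main <- which(comp == which.max(tabulate(comp)))
  v <- rep(0, nrow(W))
  if (length(main) == 1) { v[main] <- 1; return(v) }
  x <- rep(1, length(main))
  M <- W[main, main]
  shift <- max(rowSums(M))  # ensure dominant positive eigenvalue
  for (it in seq_len(iters)) {
    x <- M %*% x + shift * x
    x <- x / sqrt(sum(x^2))
  }
  v[main] <- as.numeric(x)
  v
}

oracle_assortativity <- function(W) {
  s <- rowSums(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  a <- c(s[idx[, 1]], s[idx[, 2]])
  b <- c(s[idx[, 2]], s[idx[, 1]])
  suppressWarnings(cor(a, b))
}

# all set partitions of 1..n (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

oracle_modularity <- function(W, memb, gamma = 1) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  s <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (memb[i] == memb[j])
        q <- q + W[i, j] - gamma * s[i] * s[j] / m2
  q / m2
}

oracle_max_modularity <- function(W, gamma = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    q <- oracle_modularity(W, p, gamma)
    if (q > best) best <- q
  }
  best
}

is_connected_mat <- function(W) max(oracle_components(W)) == 1

# all labeled connected graphs on n nodes, unit weights
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ne <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^ne) - 1L) {
    W <- matrix(0, n, n)
    bits <- bitwAnd(bitwShiftR(mask, seq_len(ne) - 1L), 1L) == 1L
    if (sum(bits) < n - 1) next
    sel <- pairs[bits, , drop = FALSE]
    W[sel] <- 1
    W <- W + t(W)
    if (is_connected_mat(W)) out[[length(out) + 1L]] <- W
  }
  out
}

random_connected_weighted <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    vals <- ifelse(runif(sum(up)) < p, runif(sum(up), 0.1, 1), 0)
    W[up] <- vals
    W <- W + t(W)
    if (is_connected_mat(W)) return(W)
  }
}
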