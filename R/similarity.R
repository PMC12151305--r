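# Edge consistency/variability fingerprinting and cosine matrix similarity.

#' Edge consistency / variability across participants
#'
#' Computes the standard deviation of every multilayer edge weight across
#' participants on the raw (unthresholded, unnormalized) Fisher-z matrices,
#' selects the `fraction` of edges with the lowest (`consistency`) or
#' highest (`variability`) standard deviation (`floor(fraction * E)` edges,
#' ties broken by ascending edge index), and tabulates the selected edges by
#' layer block. Block percentages are 100 x count / selected. Per-layer
#' totals assign within-layer blocks fully to their layer and split each
#' between-layer block half-and-half between its two layers, so the
#' per-layer totals also sum to 100.
#'
#' @param mats list of multilayer [connectivity_matrix()] objects (or plain
#'   matrices) with identical node labels, one per participant.
#' @param mode `"consistency"` or `"variability"`.
#' @param fraction fraction of edges to select (default 0.05).
#' @param channels node labels (`roi_id`, `depth`); taken from the first
#'   matrix when it is a [connectivity_matrix()].
#' @return An object of class `edge_dispersion` with `mode`, `block_count`,
#'   `block_pct` (D x D, upper triangle including diagonal), `per_layer_pct`,
#'   `n_selected` and the selected edge indices.
#' @export
edge_dispersion <- function(mats, mode = c("consistency", "variability"),
                            fraction = 0.05, channels = NULL) {
  mode <- match.arg(mode)
  if (length(mats) < 2) stop_invalid("invalid-argument: need >= 2 participants")
  if (is.null(channels)) {
    if (!inherits(mats[[1L]], "connectivity_matrix")) {
      stop_invalid("invalid-argument: supply channels for plain matrices")
    }
    channels <- mats[[1L]]$channels
  }
  Ws <- lapply(mats, as_weight_matrix)
  n <- nrow(Ws[[1L]])
  for (W in Ws) {
    if (!identical(dim(W), dim(Ws[[1L]]))) {
      stop_invalid("incompatible-input: matrices differ in shape")
    }
  }
  pairs <- upper_tri_pairs(n)
  vecs <- vapply(Ws, function(W) W[pairs], numeric(nrow(pairs)))
  sds <- apply(vecs, 1L, sd)
  n_sel <- floor(fraction * nrow(pairs))
  if (n_sel < 1) stop_invalid("invalid-argument: fraction selects no edges")
  ord <- if (mode == "consistency") {
    order(sds, seq_along(sds))
  } else {
    order(-sds, seq_along(sds))
  }
  sel <- ord[seq_len(n_sel)]
  di <- channels$depth[pairs[sel, 1L]]
  dj <- channels$depth[pairs[sel, 2L]]
  lo <- pmin(di, dj)
  hi <- pmax(di, dj)
  depths <- sort(unique(channels$depth))
  D <- length(depths)
  count <- matrix(0L, D, D, dimnames = list(paste0("layer", depths),
                                            paste0("layer", depths)))
  li <- match(lo, depths)
  hj <- match(hi, depths)
  for (k in seq_along(sel)) {
    count[li[k], hj[k]] <- count[li[k], hj[k]] + 1L
  }
  pct <- 100 * count / n_sel
  per_layer <- vapply(seq_len(D), function(l) {
    within <- pct[l, l]
    between <- sum(pct[l, -l]) + sum(pct[-l, l])
    within + between / 2
  }, 0)
  names(per_layer) <- paste0("layer", depths)
  structure(list(mode = mode, block_count = count, block_pct = pct,
                 per_layer_pct = per_layer, n_selected = n_sel,
                 selected_edges = pairs[sel, , drop = FALSE],
                 edge_sd = sds),
            class = "edge_dispersion")
}

#' @export
print.edge_dispersion <- function(x, ...) {
  cat(sprintf("edge_dispersion [%s]: %d edges selected\nper-layer %%:\n",
              x$mode, x$n_selected))
  print(round(x$per_layer_pct, 2))
  invisible(x)
}

#' Cosine similarity between two adjacency matrices
#'
#' Cosine of the vectors of upper-triangular weights:
#' `CS = <x_a, x_b> / (||x_a|| ||x_b||)`, in \[-1, 1\].
#'
#' @param a,b matrices (or [connectivity_matrix()]) of identical shape.
#' @return Cosine similarity, or `NA` (with warning) when either
#'   upper-triangular vector is all zeros.
#' @export
cosine_similarity <- function(a, b) {
  A <- as_weight_matrix(a)
  B <- as_weight_matrix(b)
  if (!identical(dim(A), dim(B))) {
    stop_invalid("incompatible-input: matrices differ in shape")
  }
  x <- A[upper.tri(A)]
  y <- B[upper.tri(B)]
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("undefined-result: zero upper-triangular vector")
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

#' Cosine similarity between matrix-generation methods across thresholds
#'
#' For one participant, compares the layer-by-layer matrix of each depth
#' with the within-layer block extracted from the thresholded multilayer
#' matrix, at every density of the grid; summarizes each layer's similarity
#' profile with its trapezoidal AUC.
#'
#' @param layer_by_layer list of unthresholded layer-by-layer
#'   [connectivity_matrix()] objects (Fisher-z weights), one per depth.
#' @param multilayer the participant's unthresholded multilayer
#'   [connectivity_matrix()].
#' @param grid density grid.
#' @return List with `similarity` (layer x grid matrix), `auc` (per layer),
#'   `grid`.
#' @export
method_similarity_curves <- function(layer_by_layer, multilayer,
                                     grid = density_grid()) {
  if (is.null(layer_by_layer) || is.null(multilayer)) {
    stop_invalid("incompatible-input: both pipelines are required")
  }
  depths <- sort(unique(multilayer$channels$depth))
  if (length(layer_by_layer) != length(depths)) {
    stop_invalid("incompatible-input: %d layer matrices for %d depths",
                 length(layer_by_layer), length(depths))
  }
  ml_norm <- normalize_weights(multilayer)
  lbl_norm <- lapply(layer_by_layer, normalize_weights)
  sim <- matrix(NA_real_, length(depths), length(grid),
                dimnames = list(paste0("layer", depths),
                                sprintf("d%.2f", grid)))
  for (gi in seq_along(grid)) {
    ml_thr <- threshold_proportional(ml_norm, grid[gi])
    for (d in seq_along(depths)) {
      within <- extract_within_layer(ml_thr, depths[d])
      lbl_thr <- threshold_proportional(lbl_norm[[d]], grid[gi])
      sim[d, gi] <- suppressWarnings(cosine_similarity(lbl_thr, within))
    }
  }
  list(similarity = sim,
       auc = apply(sim, 1L, auc_over_grid, grid = grid),
       grid = grid)
}
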