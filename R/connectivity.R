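#' Connectivity matrix container
#'
#' A square symmetric weighted adjacency matrix with layer-tagged nodes and
#' a pipeline tag recording how it was built.
#'
#' @param weights N x N symmetric numeric matrix with zero diagonal.
#' @param channels `data.frame` with `roi_id` and `depth` per node, in order.
#' @param pipeline_tag one of `"layer_by_layer"`, `"multilayer"`,
#'   `"within_layer"`, `"between_layer"`.
#' @param density realized edge fraction (`NA` for unthresholded matrices).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, channels,
                                pipeline_tag = c("multilayer",
                                                 "layer_by_layer",
                                                 "within_layer",
                                                 "between_layer"),
                                density = NA_real_) {
  pipeline_tag <- match.arg(pipeline_tag)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop_invalid("invalid-argument: weights not square")
  if (nrow(channels) != n) {
    stop_invalid("incompatible-input: %d nodes vs %d channel labels",
                 n, nrow(channels))
  }
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop_invalid("invalid-argument: weights not symmetric")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(channel_labels(channels), channel_labels(channels))
  structure(list(weights = weights, channels = channels,
                 pipeline_tag = pipeline_tag, density = density),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix [%s]: %d nodes, density %s\n",
              x$pipeline_tag, nrow(x$weights),
              ifelse(is.na(x$density), "unthresholded",
                     sprintf("%.3f", x$density))))
  invisible(x)
}

# accept either a connectivity_matrix or a plain symmetric matrix
as_weight_matrix <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$weights else as.matrix(x)
}

edge_count <- function(W) sum(W[upper.tri(W)] != 0)

realized_density <- function(W) {
  n <- nrow(W)
  edge_count(W) / (n * (n - 1) / 2)
}

#' Density grid for proportional thresholding
#'
#' The canonical grid: graph densities from 2% to 40% in 2% steps
#' (20 values), expressed as fractions.
#'
#' @param from,to,by grid limits and step, as fractions.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(from = 0.02, to = 0.40, by = 0.02) {
  g <- seq(round(from / by), round(to / by)) * by
  if (any(g <= 0) || any(g > 1) || any(diff(g) <= 0)) {
    stop_invalid("invalid-argument: densities must be strictly increasing in (0, 1]")
  }
  g
}

#' Fisher-z correlation matrix
#'
#' Pairwise Pearson correlations between the selected channels, normalized
#' by Fisher's z-transformation (`atanh`), with |r| clamped to `1 - 1e-7`
#' so perfectly correlated channels stay finite. Diagonal is zero.
#'
#' @param ts a [laminar_ts()] (already conditioned).
#' @param channel_idx integer indices of channels to use (default: all).
#' @param pipeline_tag tag recorded on the result.
#' @return A [connectivity_matrix()] of z-weights (unthresholded).
#' @export
correlation_fisher <- function(ts, channel_idx = NULL,
                               pipeline_tag = "multilayer") {
  data <- ts$data
  if (!is.null(channel_idx)) data <- data[, channel_idx, drop = FALSE]
  if (nrow(data) < 3) stop_invalid("invalid-argument: need T >= 3")
  if (ncol(data) < 2) stop_invalid("invalid-argument: need >= 2 channels")
  sds <- apply(data, 2L, sd)
  if (any(sds == 0)) {
    stop_invalid("zero-variance channel(s): %s",
                 paste(colnames(data)[sds == 0], collapse = ", "))
  }
  r <- cor(data)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  channels <- ts$channels
  if (!is.null(channel_idx)) channels <- channels[channel_idx, , drop = FALSE]
  connectivity_matrix(z, channels, pipeline_tag)
}

#' Layer-by-layer connectivity matrices
#'
#' One R x R Fisher-z correlation matrix per cortical depth, using only the
#' channels of that depth (R(R-1)/2 unique ROI pairs each).
#'
#' @param ts a [laminar_ts()].
#' @return Named list (`layer1`, ...) of [connectivity_matrix()] objects.
#' @export
build_layer_by_layer <- function(ts) {
  depths <- sort(unique(ts$channels$depth))
  check_full_grid(ts)
  out <- lapply(depths, function(d) {
    idx <- which(ts$channels$depth == d)
    correlation_fisher(ts, idx, pipeline_tag = "layer_by_layer")
  })
  names(out) <- paste0("layer", depths)
  out
}

#' Multilayer (supra-adjacency) connectivity matrix
#'
#' One (R*D) x (R*D) Fisher-z correlation matrix over all within- and
#' between-depth channel pairs, nodes in depth-major order (nodes 1..R are
#' layer 1).
#'
#' @param ts a [laminar_ts()].
#' @return A [connectivity_matrix()] tagged `multilayer`.
#' @export
build_multilayer <- function(ts) {
  check_full_grid(ts)
  ord <- order(ts$channels$depth, ts$channels$roi_id)
  correlation_fisher(ts, ord, pipeline_tag = "multilayer")
}

check_full_grid <- function(ts) {
  tab <- table(ts$channels$roi_id, ts$channels$depth)
  if (any(tab != 1L)) {
    stop_invalid("incompatible-input: channels do not cover every ROI x depth exactly once")
  }
  invisible(TRUE)
}

#' Normalize connection weights
#'
#' Zeroes negative weights (only positive correlations are analysed), then
#' rescales by the maximum weight so the strongest connection is 1.
#'
#' @param cm a [connectivity_matrix()].
#' @return A [connectivity_matrix()] with weights in \[0, 1\].
#' @export
normalize_weights <- function(cm) {
  W <- as_weight_matrix(cm)
  W[W < 0] <- 0
  mx <- max(W)
  if (mx <= 0) stop_invalid("degenerate-input: no positive weights to normalize")
  connectivity_matrix(W / mx, cm$channels, cm$pipeline_tag, cm$density)
}

#' Proportional thresholding to a target graph density
#'
#' Retains the `k = round(density * N(N-1)/2)` largest positive weights
#' (round half away from zero; ties broken by ascending node-index order)
#' and zeroes the rest. If fewer than `k` positive weights exist, all
#' positive weights are kept with a warning. The realized density is
#' recorded on the result.
#'
#' @param cm a normalized [connectivity_matrix()].
#' @param density target edge fraction in (0, 1\].
#' @return A thresholded [connectivity_matrix()].
#' @export
threshold_proportional <- function(cm, density) {
  if (density <= 0 || density > 1) {
    stop_invalid("invalid-argument: density must lie in (0, 1]")
  }
  W <- as_weight_matrix(cm)
  n <- nrow(W)
  pairs <- upper_tri_pairs(n)
  w <- W[pairs]
  k <- round_half_up(density * nrow(pairs))
  pos <- which(w > 0)
  if (length(pos) < k) {
    warning(sprintf("only %d positive weights available for k = %d; keeping all",
                    length(pos), k))
    keep <- pos
  } else {
    ord <- pos[order(-w[pos], pairs[pos, 1L], pairs[pos, 2L])]
    keep <- ord[seq_len(k)]
  }
  Wt <- matrix(0, n, n)
  kp <- pairs[keep, , drop = FALSE]
  Wt[kp] <- w[keep]
  Wt <- Wt + t(Wt)
  connectivity_matrix(Wt, cm$channels, cm$pipeline_tag,
                      density = length(keep) / nrow(pairs))
}

#' Extract the within-layer block of a thresholded multilayer matrix
#'
#' Returns the R x R diagonal block of the supra-adjacency matrix for one
#' depth (e.g. nodes 1..R for layer 1). The per-layer realized density of
#' these blocks may differ across depths — that difference is informative.
#'
#' @param cm a thresholded [connectivity_matrix()] tagged `multilayer`.
#' @param layer depth index.
#' @return A [connectivity_matrix()] tagged `within_layer`.
#' @export
extract_within_layer <- function(cm, layer) {
  if (cm$pipeline_tag != "multilayer") {
    stop_invalid("invalid-argument: input must be a multilayer matrix")
  }
  idx <- which(cm$channels$depth == layer)
  if (length(idx) == 0) stop_invalid("invalid-argument: layer %s out of range", layer)
  W <- cm$weights[idx, idx, drop = FALSE]
  out <- connectivity_matrix(W, cm$channels[idx, , drop = FALSE],
                             "within_layer")
  out$density <- realized_density(W)
  out
}

#' Zero the within-layer blocks of a thresholded multilayer matrix
#'
#' Keeps only between-depth connections: all D within-depth diagonal blocks
#' are set to zero.
#'
#' @param cm a thresholded [connectivity_matrix()] tagged `multilayer`.
#' @return A [connectivity_matrix()] tagged `between_layer`, same shape.
#' @export
extract_between_layer <- function(cm) {
  if (cm$pipeline_tag != "multilayer") {
    stop_invalid("invalid-argument: input must be a multilayer matrix")
  }
  W <- cm$weights
  same <- outer(cm$channels$depth, cm$channels$depth, `==`)
  W[same] <- 0
  out <- connectivity_matrix(W, cm$channels, "between_layer")
  out$density <- realized_density(W)
  out
}

#' Write / read a connectivity matrix as TSV (+ JSON sidecar)
#'
#' @param cm a [connectivity_matrix()].
#' @param path TSV path; a `.json` sidecar with the pipeline tag and
#'   realized density is written alongside.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(cm, path) {
  write.table(cm$weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(pipeline_tag = cm$pipeline_tag,
                            density = cm$density,
                            n_nodes = nrow(cm$weights)),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}
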