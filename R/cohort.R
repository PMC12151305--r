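# Cohort-level drivers: conditioned time series -> per-pipeline AUC tables
# ready for layer-wise comparison.

#' Measure curves for within-layer blocks of a multilayer matrix
#'
#' Thresholds the normalized supra-adjacency matrix at every density of the
#' grid, extracts each depth's within-layer block (so per-layer density is
#' free to differ — the laminar signal of interest), and computes the
#' requested measures per layer, with trapezoidal AUC.
#'
#' @param ml_norm normalized, unthresholded multilayer
#'   [connectivity_matrix()].
#' @inheritParams measure_curves
#' @return List with one element per layer, each as in [measure_curves()].
#' @export
within_layer_measure_curves <- function(ml_norm, grid = density_grid(),
                                        global_measures = default_global_measures(),
                                        nodal_measures = character(),
                                        gamma = 1, n_restarts = 10, seed = 1L) {
  depths <- sort(unique(ml_norm$channels$depth))
  snaps <- lapply(grid, function(d) {
    thr <- threshold_proportional(ml_norm, d)
    lapply(depths, function(dep) {
      block <- extract_within_layer(thr, dep)
      measure_snapshot(block, global_measures, nodal_measures,
                       gamma, n_restarts, seed)
    })
  })
  out <- lapply(seq_along(depths), function(di) {
    layer_snaps <- lapply(snaps, `[[`, di)
    res <- list(grid = grid)
    if (length(global_measures)) {
      vals <- vapply(layer_snaps, function(s) s$global[global_measures],
                     numeric(length(global_measures)))
      vals <- matrix(vals, nrow = length(global_measures),
                     dimnames = list(global_measures, NULL))
      res$global <- data.frame(
        measure = global_measures, vals,
        auc = apply(vals, 1L, auc_over_grid, grid = grid),
        check.names = FALSE, row.names = NULL)
      colnames(res$global)[2:(1 + length(grid))] <- sprintf("d%.2f", grid)
    }
    if (length(nodal_measures)) {
      nn <- sum(ml_norm$channels$depth == depths[di])
      res$nodal <- lapply(nodal_measures, function(m) {
        mat <- vapply(layer_snaps, function(s) s$nodal[[m]], numeric(nn))
        list(values = mat, auc = apply(mat, 1L, auc_over_grid, grid = grid))
      })
      names(res$nodal) <- nodal_measures
    }
    res
  })
  names(out) <- paste0("layer", depths)
  out
}

#' Long-format AUC table for a conditioned cohort
#'
#' Runs the chosen matrix pipeline for every participant and returns the
#' threshold-free AUC of each measure per layer, in the long format
#' consumed by [compare_layers()].
#'
#' @param cohort list of conditioned [laminar_ts()] objects.
#' @param pipeline `"layer_by_layer"` (each depth correlated and
#'   thresholded independently) or `"within_layer"` (blocks of the
#'   thresholded supra-adjacency matrix).
#' @inheritParams measure_curves
#' @return `data.frame` with columns `participant`, `pipeline`, `measure`,
#'   `layer`, `auc`, and `node` (`NA` for global rows) plus `scope`.
#' @export
cohort_auc_table <- function(cohort,
                             pipeline = c("layer_by_layer", "within_layer"),
                             grid = density_grid(),
                             global_measures = default_global_measures(),
                             nodal_measures = character(),
                             gamma = 1, n_restarts = 10, seed = 1L) {
  pipeline <- match.arg(pipeline)
  rows <- lapply(cohort, function(ts) {
    pid <- ts$participant_id
    depths <- sort(unique(ts$channels$depth))
    if (pipeline == "layer_by_layer") {
      lbl <- build_layer_by_layer(ts)
      per_layer <- lapply(seq_along(depths), function(di) {
        measure_curves(normalize_weights(lbl[[di]]), grid,
                       global_measures, nodal_measures,
                       gamma, n_restarts, seed)
      })
    } else {
      ml <- normalize_weights(build_multilayer(ts))
      per_layer <- within_layer_measure_curves(ml, grid, global_measures,
                                               nodal_measures,
                                               gamma, n_restarts, seed)
    }
    do.call(rbind, lapply(seq_along(depths), function(di) {
      res <- per_layer[[di]]
      roi_ids <- ts$channels$roi_id[ts$channels$depth == depths[di]]
      parts <- list()
      if (!is.null(res$global)) {
        parts$global <- data.frame(
          participant = pid, pipeline = pipeline, scope = "global",
          measure = res$global$measure, layer = depths[di],
          node = NA_integer_, auc = res$global$auc,
          stringsAsFactors = FALSE)
      }
      if (!is.null(res$nodal)) {
        parts$nodal <- do.call(rbind, lapply(names(res$nodal), function(m) {
          data.frame(participant = pid, pipeline = pipeline, scope = "nodal",
                     measure = m, layer = depths[di], node = roi_ids,
                     auc = res$nodal[[m]]$auc, stringsAsFactors = FALSE)
        }))
      }
      do.call(rbind, parts)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
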