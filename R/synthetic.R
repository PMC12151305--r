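#' Effect specification for the synthetic laminar generator
#'
#' Bundles the parameters that control planted laminar structure in the
#' synthetic cohorts. The generative model is latent-factor linear-Gaussian:
#' each cortical depth carries a planted ROI graph; connected ROIs share
#' latent signal, shallower depths additionally receive a leakage mixture of
#' all strictly deeper signals of the same ROI (emulating the superficial
#' draining-vein bias of gradient-echo BOLD), and white Gaussian noise is
#' added per channel.
#'
#' Within-layer planted edge probability at depth `d` of `D` is
#' `edge_prob_base * (1 + density_gradient * (1 - 2*(d-1)/(D-1)))`, so a
#' positive gradient makes superficial layers denser. Layer graphs are nested
#' (one uniform draw per candidate edge shared by all depths), which makes
#' `density_gradient = 0` produce layer-identical topology — an exact null in
#' which the depths are exchangeable.
#'
#' @param density_gradient real in \[-1, 1\]; monotone density change from
#'   superficial (layer 1) to deep (layer `D`).
#' @param leakage_lambda real in \[0, 1); fraction of the mean strictly-deeper
#'   latent signal mixed into each shallower channel of the same ROI.
#' @param noise_sd positive real; sd of additive channel noise.
#' @param edge_prob_base real in (0, 1); mid-depth planted edge probability.
#' @param effect_strength positive real; loading of shared edge factors
#'   (latent signal is `(I + effect_strength * A) %*% noise_basis`).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(density_gradient = 0.5, leakage_lambda = 0.2,
                        noise_sd = 1.0, edge_prob_base = 0.10,
                        effect_strength = 0.25) {
  if (abs(density_gradient) > 1) {
    stop_invalid("invalid-argument: density_gradient must lie in [-1, 1]")
  }
  if (leakage_lambda < 0 || leakage_lambda >= 1) {
    stop_invalid("invalid-argument: leakage_lambda must lie in [0, 1)")
  }
  if (noise_sd < 0) stop_invalid("invalid-argument: noise_sd must be >= 0")
  if (edge_prob_base <= 0 || edge_prob_base >= 1) {
    stop_invalid("invalid-argument: edge_prob_base must lie in (0, 1)")
  }
  if (effect_strength < 0) {
    stop_invalid("invalid-argument: effect_strength must be >= 0")
  }
  structure(list(density_gradient = density_gradient,
                 leakage_lambda = leakage_lambda,
                 noise_sd = noise_sd,
                 edge_prob_base = edge_prob_base,
                 effect_strength = effect_strength),
            class = "effect_spec")
}

#' Laminar time-series container
#'
#' @param participant_id label.
#' @param data numeric matrix, time points x (ROI, depth) channels, in
#'   depth-major order (channels 1..R are depth 1, the most superficial).
#' @param channels `data.frame` with columns `roi_id` and `depth` describing
#'   each column of `data`, in order.
#' @param tr_seconds positive sampling interval (s).
#' @return An object of class `laminar_ts`.
#' @export
laminar_ts <- function(participant_id, data, channels, tr_seconds) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop_invalid("invalid-argument: need T >= 2 time points")
  if (ncol(data) != nrow(channels)) {
    stop_invalid("incompatible-input: %d data columns vs %d channel labels",
                 ncol(data), nrow(channels))
  }
  if (tr_seconds <= 0) stop_invalid("invalid-argument: tr_seconds must be > 0")
  colnames(data) <- channel_labels(channels)
  structure(list(participant_id = participant_id, data = data,
                 channels = channels, tr_seconds = tr_seconds),
            class = "laminar_ts")
}

channel_labels <- function(channels) {
  sprintf("roi%03d_depth%d", channels$roi_id, channels$depth)
}

#' @export
print.laminar_ts <- function(x, ...) {
  cat(sprintf("laminar_ts '%s': %d time points x %d channels (%d ROIs x %d depths), TR %.3g s\n",
              x$participant_id, nrow(x$data), ncol(x$data),
              length(unique(x$channels$roi_id)),
              length(unique(x$channels$depth)), x$tr_seconds))
  invisible(x)
}

# Nested planted layer graphs: one uniform draw per ROI pair, reused across
# depths, so the depth-d edge set is {e : u_e < p_d}. Marginal edge
# probability at depth d is exactly p_d and the edge sets are nested along
# the density gradient.
plant_layer_graphs <- function(n_roi, n_depths, effect, seed) {
  p <- layer_edge_prob(effect, n_depths)
  pairs <- upper_tri_pairs(n_roi)
  with_seed(seed, {
    u <- runif(nrow(pairs))
    lapply(seq_len(n_depths), function(d) {
      A <- matrix(0, n_roi, n_roi)
      keep <- u < p[d]
      A[pairs[keep, , drop = FALSE]] <- 1
      A + t(A)
    })
  })
}

layer_edge_prob <- function(effect, n_depths) {
  d <- seq_len(n_depths)
  p <- effect$edge_prob_base *
    (1 + effect$density_gradient * (1 - 2 * (d - 1) / (n_depths - 1)))
  pmin(pmax(p, 0), 1)
}

# Latent ROI factor signals per depth: L_d = eps_d (I + gamma * A_d) with
# iid standard normal basis eps_d (T x R). Known covariance
# (I + gamma A)'(I + gamma A), always positive definite.
draw_latent <- function(n_roi, n_depths, n_timepoints, effect, graphs, seed) {
  gamma <- effect$effect_strength
  with_seed(seed, {
    lapply(seq_len(n_depths), function(d) {
      eps <- matrix(rnorm(n_timepoints * n_roi), n_timepoints, n_roi)
      if (gamma > 0) eps + gamma * (eps %*% graphs[[d]]) else eps
    })
  })
}

#' Generate one synthetic participant
#'
#' Simulates depth-resolved ROI time series with planted laminar network
#' structure (see [effect_spec()] for the generative model). The observed
#' channel at depth `d` is the depth-`d` latent ROI signal plus
#' `leakage_lambda` times the mean of the same ROI's strictly deeper latent
#' signals, plus Gaussian noise. Deterministic given its arguments.
#'
#' @param atlas atlas `data.frame` from [generate_atlas()].
#' @param n_depths number of cortical depths (>= 2); depth 1 is superficial.
#' @param n_timepoints number of time points; must be at least 10 times the
#'   number of latent factors per layer (i.e. `10 * nrow(atlas)`).
#' @param tr_seconds sampling interval in seconds.
#' @param effect an [effect_spec()].
#' @param seed integer seed.
#' @param participant_id label; default `"sub-<seed>"`.
#' @param graphs optional pre-drawn planted layer graphs (used by
#'   [generate_cohort()] to share topology across participants).
#' @param latent optional pre-drawn latent signals (shared-latent cohorts).
#' @return A [laminar_ts()].
#' @export
generate_participant <- function(atlas, n_depths = 5, n_timepoints = 2028,
                                 tr_seconds = 2.8, effect = effect_spec(),
                                 seed = 1L, participant_id = NULL,
                                 graphs = NULL, latent = NULL) {
  n_roi <- nrow(atlas)
  if (n_depths < 2) stop_invalid("invalid-argument: n_depths must be >= 2")
  if (n_timepoints < 10 * n_roi) {
    stop_invalid(
      "invalid-argument: n_timepoints (%d) must be >= 10 x latent factors per layer (%d)",
      n_timepoints, 10 * n_roi)
  }
  seeds <- derive_seeds(seed, 3L)
  if (is.null(graphs)) {
    graphs <- plant_layer_graphs(n_roi, n_depths, effect, seeds[1L])
  }
  if (is.null(latent)) {
    latent <- draw_latent(n_roi, n_depths, n_timepoints, effect, graphs,
                          seeds[2L])
  }
  lam <- effect$leakage_lambda
  observed <- vector("list", n_depths)
  for (d in seq_len(n_depths)) {
    y <- latent[[d]]
    if (lam > 0 && d < n_depths) {
      deeper <- Reduce(`+`, latent[(d + 1):n_depths]) / (n_depths - d)
      y <- y + lam * deeper
    }
    observed[[d]] <- y
  }
  data <- do.call(cbind, observed)
  if (effect$noise_sd > 0) {
    noise <- with_seed(seeds[3L], {
      matrix(rnorm(length(data), sd = effect$noise_sd), nrow(data), ncol(data))
    })
    data <- data + noise
  }
  channels <- data.frame(
    roi_id = rep(atlas$roi_id, times = n_depths),
    depth = rep(seq_len(n_depths), each = n_roi)
  )
  if (is.null(participant_id)) participant_id <- sprintf("sub-%d", seed)
  laminar_ts(participant_id, data, channels, tr_seconds)
}

#' Generate a synthetic cohort
#'
#' Participants share the planted layer-graph topology (drawn once from the
#' master seed); each participant receives independent latent signals and
#' noise by default, so layer comparisons across participants are valid
#' replicates. With `share_latent = TRUE` the latent ROI signals themselves
#' are shared and participants differ only by leakage/noise.
#'
#' @inheritParams generate_participant
#' @param n_participants integer >= 2.
#' @param share_latent logical; share latent signals across participants.
#' @return List of [laminar_ts()] objects with attribute `"graphs"` carrying
#'   the planted layer adjacency matrices.
#' @export
generate_cohort <- function(atlas, n_participants = 30, n_depths = 5,
                            n_timepoints = 2028, tr_seconds = 2.8,
                            effect = effect_spec(), seed = 42L,
                            share_latent = FALSE) {
  if (n_participants < 2) {
    stop_invalid("invalid-argument: n_participants must be >= 2")
  }
  seeds <- derive_seeds(seed, n_participants + 2L)
  graphs <- plant_layer_graphs(nrow(atlas), n_depths, effect, seeds[1L])
  latent <- NULL
  if (share_latent) {
    latent <- draw_latent(nrow(atlas), n_depths, n_timepoints, effect, graphs,
                          seeds[2L])
  }
  cohort <- lapply(seq_len(n_participants), function(i) {
    generate_participant(atlas, n_depths, n_timepoints, tr_seconds, effect,
                         seed = seeds[i + 2L],
                         participant_id = sprintf("sub-%02d", i),
                         graphs = graphs, latent = latent)
  })
  attr(cohort, "graphs") <- graphs
  cohort
}

#' Write / read laminar time series as TSV
#'
#' One row per time point; header row gives `roi<ID>_depth<K>` channel
#' labels in depth-major order.
#'
#' @param ts a [laminar_ts()].
#' @param path file path.
#' @param tr_seconds,participant_id metadata restored on read (the TSV holds
#'   only the data matrix and labels).
#' @return `write_laminar_tsv` returns `path` invisibly; `read_laminar_tsv`
#'   returns a [laminar_ts()].
#' @export
write_laminar_tsv <- function(ts, path) {
  write.table(ts$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_laminar_tsv
#' @export
read_laminar_tsv <- function(path, tr_seconds, participant_id = basename(path)) {
  data <- as.matrix(read.delim(path, check.names = FALSE))
  labels <- colnames(data)
  m <- regmatches(labels, regexec("^roi([0-9]+)_depth([0-9]+)$", labels))
  if (any(lengths(m) != 3L)) {
    stop_invalid("incompatible-input: malformed channel labels in %s", path)
  }
  channels <- data.frame(
    roi_id = as.integer(vapply(m, `[`, "", 2L)),
    depth = as.integer(vapply(m, `[`, "", 3L))
  )
  laminar_ts(participant_id, data, channels, tr_seconds)
}

#' Write a cohort to a directory (per-participant TSVs + manifest)
#'
#' @param cohort list of [laminar_ts()].
#' @param atlas atlas table.
#' @param dir output directory (created if absent).
#' @return Path of the JSON manifest, invisibly.
#' @export
write_cohort <- function(cohort, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas_tsv(atlas, file.path(dir, "atlas.tsv"))
  files <- vapply(cohort, function(ts) {
    f <- sprintf("%s_timeseries.tsv", ts$participant_id)
    write_laminar_tsv(ts, file.path(dir, f))
    f
  }, "")
  manifest <- list(
    participants = vapply(cohort, `[[`, "", "participant_id"),
    files = files,
    tr_seconds = cohort[[1L]]$tr_seconds,
    n_timepoints = nrow(cohort[[1L]]$data),
    n_roi = length(unique(cohort[[1L]]$channels$roi_id)),
    n_depths = length(unique(cohort[[1L]]$channels$depth)),
    atlas = "atlas.tsv"
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param dir directory containing `manifest.json`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort <- Map(function(f, id) {
    read_laminar_tsv(file.path(dir, f), manifest$tr_seconds, id)
  }, manifest$files, manifest$participants)
  names(cohort) <- manifest$participants
  attr(cohort, "atlas") <- read_atlas_tsv(file.path(dir, manifest$atlas))
  cohort
}
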