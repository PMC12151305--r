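# Config-driven end-to-end runner: synth -> preprocess -> construct ->
# measures/AUC -> dispersion & similarity -> layer statistics -> tabulation.

default_config <- function() {
  list(
    synthetic = list(n_participants = 10, n_roi = 40, n_depths = 3,
                     n_timepoints = 400, tr_seconds = 2.8,
                     effect = list(density_gradient = 0.5,
                                   leakage_lambda = 0.2, noise_sd = 1.0,
                                   edge_prob_base = 0.10,
                                   effect_strength = 0.25)),
    input_dir = NULL,
    out_dir = "laminarnet-out",
    filter = list(highpass_hz = 0.01, lowpass_hz = 0.1, order = 2),
    grid = list(from = 0.02, to = 0.40, by = 0.02),
    pipelines = c("layer_by_layer", "within_layer"),
    global_measures = default_global_measures(),
    nodal_measures = character(),
    dispersion_fraction = 0.05,
    stats = list(global_method = "benjamini_hochberg", global_alpha = 0.05,
                 nodal_method = "holm", nodal_alpha = 0.01),
    community = list(gamma = 1, n_restarts = 10),
    seed = 42
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

# FNV-1a over the serialized config, for output provenance; the output
# location does not change what is computed, so it is excluded
config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h itself can exceed 2^31 so it
    # must stay numeric, out of bitwXor's integer range
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

#' Run the full laminar connectomics pipeline
#'
#' Executes, in order: synthetic-cohort generation (or cohort loading from
#' `input_dir`), detrend + zero-phase band-pass conditioning, construction
#' of the layer-by-layer and multilayer matrices, threshold-free measure
#' AUC tables per pipeline, edge consistency/variability, method cosine
#' similarity, layer-wise ANOVA with multiple-comparison control, and
#' (when nodal measures are configured) region tabulation plus the cortical
#' thickness confound test. All outputs are TSV/JSON under `out_dir`,
#' stamped with the config hash and seed. Idempotent given fixed seeds.
#'
#' @param config a config list or path to a YAML config; unset fields take
#'   the documented defaults (`laminarnet:::default_config()`).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with the in-memory results (`auc_tables`,
#'   `stats`, `dispersion`, `similarity_auc`, paths and provenance).
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  hash <- config_hash(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[laminarnet %s] ", hash),
                                   sprintf(...))
  stamp <- function(name) file.path(out_dir, sprintf("%s_%s", hash, name))

  # stage 1: cohort
  if (!is.null(cfg$input_dir)) {
    log_msg("loading cohort from %s", cfg$input_dir)
    cohort <- read_cohort(cfg$input_dir)
    atlas <- attr(cohort, "atlas")
  } else {
    sc <- cfg$synthetic
    log_msg("generating cohort: %d participants x %d ROIs x %d depths x %d timepoints",
            sc$n_participants, sc$n_roi, sc$n_depths, sc$n_timepoints)
    atlas <- generate_atlas(sc$n_roi, seed = cfg$seed)
    effect <- do.call(effect_spec, sc$effect)
    cohort <- generate_cohort(atlas, sc$n_participants, sc$n_depths,
                              sc$n_timepoints, sc$tr_seconds, effect,
                              seed = cfg$seed)
  }

  # stage 2: conditioning
  log_msg("conditioning time series (detrend + zero-phase band-pass)")
  fspec <- do.call(filter_spec, cfg$filter)
  cohort <- lapply(cohort, detrend_bandpass, spec = fspec)

  grid <- do.call(density_grid, cfg$grid)

  # stage 3: dispersion + similarity on raw multilayer z matrices
  log_msg("building multilayer matrices; edge dispersion and method similarity")
  mls <- lapply(cohort, build_multilayer)
  dispersion <- list(
    consistency = edge_dispersion(mls, "consistency", cfg$dispersion_fraction),
    variability = edge_dispersion(mls, "variability", cfg$dispersion_fraction)
  )
  for (mode in names(dispersion)) {
    dd <- dispersion[[mode]]
    write.table(cbind(data.frame(block = rownames(dd$block_pct)),
                      as.data.frame(dd$block_pct)),
                stamp(sprintf("edge_%s_blocks.tsv", mode)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(layer = names(dd$per_layer_pct),
                           pct = dd$per_layer_pct),
                stamp(sprintf("edge_%s_per_layer.tsv", mode)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim_auc <- t(vapply(seq_along(cohort), function(i) {
    lbl <- build_layer_by_layer(cohort[[i]])
    method_similarity_curves(lbl, mls[[i]], grid)$auc
  }, numeric(length(unique(cohort[[1L]]$channels$depth)))))
  rownames(sim_auc) <- vapply(cohort, `[[`, "", "participant_id")
  write.table(cbind(data.frame(participant = rownames(sim_auc)),
                    as.data.frame(sim_auc)),
              stamp("method_similarity_auc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4-5: measures, AUC, statistics
  auc_tables <- list()
  stats_tables <- list()
  tabulations <- list()
  thickness <- list()
  for (pl in cfg$pipelines) {
    log_msg("measure curves for pipeline '%s'", pl)
    tab <- cohort_auc_table(cohort, pl, grid,
                            global_measures = cfg$global_measures,
                            nodal_measures = cfg$nodal_measures,
                            gamma = cfg$community$gamma,
                            n_restarts = cfg$community$n_restarts,
                            seed = cfg$seed)
    auc_tables[[pl]] <- tab
    write.table(tab, stamp(sprintf("auc_%s.tsv", pl)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res_g <- compare_layers(tab[tab$scope == "global", ], "global",
                            cfg$stats$global_method, cfg$stats$global_alpha)
    res_g$pipeline <- pl
    stats_tables[[paste0(pl, "_global")]] <- res_g
    write.table(res_g, stamp(sprintf("stats_global_%s.tsv", pl)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(cfg$nodal_measures)) {
      res_n <- compare_layers(tab[tab$scope == "nodal", ], "nodal",
                              cfg$stats$nodal_method, cfg$stats$nodal_alpha)
      res_n$pipeline <- pl
      stats_tables[[paste0(pl, "_nodal")]] <- res_n
      write.table(res_n, stamp(sprintf("stats_nodal_%s.tsv", pl)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tabulations[[pl]] <- tabulate_regions(res_n, atlas)
      write.table(tabulations[[pl]], stamp(sprintf("regions_%s.tsv", pl)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      thickness[[pl]] <- thickness_confound_test(res_n, atlas)
      write.table(thickness[[pl]], stamp(sprintf("thickness_%s.tsv", pl)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # peak-layer summary grid (measure x pipeline)
  peak_grid <- do.call(rbind, lapply(names(stats_tables), function(nm) {
    st <- stats_tables[[nm]]
    st[, c("pipeline", "scope", "measure", "significant", "peak_layer")]
  }))
  provenance <- list(config = cfg, config_hash = hash, seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("laminarnet")),
                     r_version = R.version.string)
  jsonlite::write_json(provenance, stamp("run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(peak_grid, stamp("peak_layer_grid.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("done; outputs in %s", out_dir)
  invisible(list(atlas = atlas, auc_tables = auc_tables,
                 stats = stats_tables, dispersion = dispersion,
                 similarity_auc = sim_auc, tabulations = tabulations,
                 thickness = thickness, config = cfg, config_hash = hash,
                 out_dir = out_dir))
}

#' Write a deterministic demo dataset
#'
#' Generates a cohort, atlas and matching pipeline config at one of three
#' documented scales and writes them (TSV + JSON + YAML) under `dir`.
#' Scales: `tiny` = 4 participants x 10 ROIs x 2 depths x 120 time points;
#' `demo` = 10 x 40 x 3 x 400; `full` = 30 x 148 x 5 x 2028.
#'
#' @param scale `"tiny"`, `"demo"` or `"full"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return The fixture directory, invisibly.
#' @export
make_fixtures <- function(scale = c("tiny", "demo", "full"), seed = 42L,
                          dir = file.path("fixtures", scale)) {
  scale <- match.arg(scale)
  dims <- switch(scale,
                 tiny = list(p = 4, r = 10, d = 2, t = 120),
                 demo = list(p = 10, r = 40, d = 3, t = 400),
                 full = list(p = 30, r = 148, d = 5, t = 2028))
  atlas <- generate_atlas(dims$r, seed = seed)
  cohort <- generate_cohort(atlas, dims$p, dims$d, dims$t,
                            tr_seconds = 2.8, effect = effect_spec(),
                            seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, atlas, dir)
  cfg <- list(input_dir = dir, out_dir = file.path(dir, "out"), seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
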