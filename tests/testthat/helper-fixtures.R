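# Small in-code fixtures shared across test files.

tiny_atlas <- function(n = 10, seed = 7) generate_atlas(n, seed = seed)

tiny_participant <- function(n_roi = 10, n_depths = 3, n_timepoints = 150,
                             effect = effect_spec(), seed = 11) {
  generate_participant(tiny_atlas(n_roi), n_depths, n_timepoints,
                       tr_seconds = 2.8, effect = effect, seed = seed)
}

# connectivity matrix from a plain weight matrix, single layer
cm_single <- function(W, tag = "layer_by_layer") {
  connectivity_matrix(W, data.frame(roi_id = seq_len(nrow(W)) - 1L,
                                    depth = rep(1L, nrow(W))), tag)
}

# multilayer connectivity matrix from a plain weight matrix
cm_multi <- function(W, n_roi, n_depths, tag = "multilayer") {
  connectivity_matrix(W, data.frame(roi_id = rep(seq_len(n_roi) - 1L,
                                                 times = n_depths),
                                    depth = rep(seq_len(n_depths),
                                                each = n_roi)), tag)
}

# cohort of multilayer z-matrices where a chosen edge subset is identical
# across participants (sd exactly 0) and every other edge varies
planted_dispersion_cohort <- function(n_roi = 4, n_depths = 2,
                                      n_participants = 3, frozen_frac = 0.05,
                                      seed = 5) {
  n <- n_roi * n_depths
  npairs <- n * (n - 1) / 2
  n_frozen <- floor(frozen_frac * npairs)
  set.seed(seed)
  frozen <- sort(sample(npairs, n_frozen))
  base <- runif(npairs, 0.2, 0.8)
  mats <- lapply(seq_len(n_participants), function(p) {
    w <- base + runif(npairs, 0.05, 0.3) * (p - 1)  # varies unless frozen
    w[frozen] <- base[frozen]
    W <- matrix(0, n, n)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(pairs[, 1], pairs[, 2])
    W[pairs[ord, , drop = FALSE]] <- w
    W <- W + t(W)
    cm_multi(W, n_roi, n_depths)
  })
  list(mats = mats, frozen = frozen)
}

# random symmetric nonnegative matrix with zero diagonal
random_sym <- function(n, seed, negatives = FALSE) {
  set.seed(seed)
  W <- matrix(runif(n * n, -0.3 * negatives, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}
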