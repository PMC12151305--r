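---
title: "Laminar multilayer connectomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar multilayer connectomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarnet)
```

`laminarnet` analyses depth-resolved functional brain networks: every atlas
ROI contributes one channel per cortical depth, and the question is whether
graph-theoretic network organization differs systematically across depths.
This vignette documents the models the package implements, the parameters
that matter, and the design decisions taken where the methodology left
genuine freedom — so that results can be interpreted, and the choices
revisited, without reading the source.

## 1. From time series to networks

**Conditioning.** Channels are linearly detrended and band-pass filtered
0.01–0.1 Hz with a second-order Butterworth design applied forward and
backward (`detrend_bandpass()`). "Second-order" refers to the design order
before the forward–backward doubling, the conventional reading of the
zero-phase (filtfilt-style) routine. We apply our own zero-phase pass with
odd-reflection padding of three filter lengths at each end, which bounds
edge transients on short runs; the net phase is zero (verified by
cross-correlation in the test suite) and the amplitude response is the
squared Butterworth magnitude. Detrending is linear, not polynomial, and is
applied after run concatenation (`concatenate_runs()`), matching the order
of the processing description it implements; both choices are deliberate
constants rather than options buried in code.

**Connectivity.** Pairwise Pearson correlations are Fisher-z-transformed,
`z = arctanh(r)`, with `|r|` clamped at `1 - 1e-7` so perfectly correlated
channels produce large finite weights rather than infinities. Two pipelines
are built (`build_layer_by_layer()`, `build_multilayer()`): per-depth
R × R matrices, and one supra-adjacency matrix over all R·D nodes in
depth-major order (nodes 1..R are the most superficial depth). Partial
correlations are out of scope: with hundreds of nodes and a few thousand
time points they are poorly conditioned and need regularization choices of
their own.

**Normalization and thresholding.** `normalize_weights()` zeroes negative
weights (only positive couplings are analysed) and divides by the maximum
weight. The normalization formula is not uniquely determined by convention;
max-rescaling was chosen because it is the standard weight-conversion step
of the graph-analysis toolboxes this suite mirrors, and because it makes
within-/between-layer extractions scale-consistent. `threshold_proportional()`
keeps the `k = round(density · N(N−1)/2)` largest positive weights
(round-half-away-from-zero; ties broken by ascending node index for exact
reproducibility) at each density of the 2%–40%, step-2% grid. Surviving edge
sets are nested along the grid. When fewer than `k` positive weights exist,
all positives are kept and the realized density is recorded — a warning, not
an error, because sparse matrices are expected at tiny problem sizes.

The within-layer and between-layer matrices are extracted *after*
thresholding the supra matrix: the R × R diagonal block of depth d, and the
supra matrix with all D diagonal blocks zeroed. Per-layer density of these
blocks is therefore free to differ across depths — in the layer-by-layer
pipeline density is fixed by construction (each depth thresholded to the
same target), which is exactly why that pipeline cannot see laminar density
differences and the multilayer one can.

## 2. Graph measures

All measures are weighted variants (`measure_curves()` evaluates them along
the density grid): distances on edge lengths `1/weight`; clustering and
transitivity by the geometric-mean-of-triangle-weights convention; local
efficiency as the global efficiency of each node's neighborhood-induced
subgraph (paths may not leave the neighborhood — this differs from some
library implementations, and the test suite pins it against brute force);
betweenness with endpoints excluded and fractional path multiplicity;
eigenvector centrality as the unit-norm principal eigenvector of the
largest connected component, zeros elsewhere; strength assortativity as the
endpoint-strength correlation over edges (an undefined-variance sentinel
`NA` on degree-regular graphs); modularity by Louvain at resolution
γ = 1 with the best of 10 seeded restarts, and participation coefficients
`1 − Σ_m (k_im/k_i)²` against that same partition (the community assignment
is not prescribed elsewhere, so the network's own modularity partition is
used). Small-world σ uses degree-preserving weighted double-edge swaps
(100 nulls, 10 attempted swaps per edge, seeded) and is computed on demand
rather than inside the default suite: its null ensemble is two orders of
magnitude more expensive than every other measure combined.

Disconnection conventions, needed because low densities fragment the graph:
characteristic path length averages finite distances only; global
efficiency counts disconnected pairs as zero; radius and diameter are taken
over the largest component; an edgeless graph yields `NA` for
distance-based and community measures inside curve evaluation (so curves
stay rectangular) but is an explicit error in the standalone functions.
AUC (`auc_over_grid()`) is the trapezoidal rule over the density grid
expressed as fractions, exact on linear curves; `NA` values propagate to
the AUC rather than being silently dropped.

## 3. The synthetic cohort generator

No public laminar 7-T dataset accompanies this methodology, so the
generator is first-class, tested code — it defines the conditions under
which the statistical layer is validated.

The model is latent-factor linear-Gaussian. For depth d of D, a planted ROI
graph `A_d` is drawn with edge probability
`edge_prob_base · (1 + density_gradient · (1 − 2(d−1)/(D−1)))`, so a
positive gradient makes superficial depths denser. Latent ROI signals are
`L_d = ε_d (I + γ A_d)` with iid standard normal `ε_d` (T × R) and loading
γ = `effect_strength`; the covariance `(I + γA)ᵀ(I + γA)` is known and
always positive definite. The observed channel is
`y_d = L_d + λ · mean(L_{d'}: d' > d) + noise`, with `λ = leakage_lambda`
mixing strictly-deeper signal superficial-ward — the direction of the
pial draining-vein bias in gradient-echo BOLD — and Gaussian channel noise
of sd `noise_sd`. A hemodynamic simulator was deliberately not built: the
validation targets are parameter recovery and calibration, not BOLD
realism, and a linear-Gaussian model with known covariance makes the
planted truth exactly checkable.

Two structural choices deserve emphasis:

* **Nested planted graphs.** One uniform draw per candidate edge is shared
  by all depths; depth d keeps the edge iff `u < p_d`. Marginal edge
  probability is exactly `p_d`, the edge sets are nested along the
  gradient, and — critically — `density_gradient = 0` yields *identical*
  topology in every layer. The null model is then exact: within a
  participant the depths differ only by independent latent draws and noise,
  so layer labels are exchangeable and the downstream ANOVA's type-I error
  is controlled by construction. Independently drawn per-depth graphs would
  instead plant realized-topology differences between layers that every
  participant shares, inflating the layer F-test under the null.
* **Independent latent signals per participant (default).** Participants
  share the planted topology (drawn from the master seed) but draw their
  own latent signals and noise, making them valid replicates for the
  layer ANOVA. `generate_cohort(share_latent = TRUE)` switches to fully
  shared latent signals — useful for constructing deterministic cohorts
  (e.g. zero-noise identity checks) but *not* a valid null for
  across-participant inference, since participants are then correlated.

Default effect parameters (frozen once, before any calibration runs, as a
plausible laminar fMRI regime): `edge_prob_base = 0.10` (sparse anatomical
backbone), `density_gradient = 0.5` (superficial density excess, the
phenomenon of interest), `leakage_lambda = 0.2` (moderate venous drainage
mixing), `noise_sd = 1.0` (noise on the order of the latent signal,
i.e. single-channel SNR near 1), `effect_strength = 0.25` (planted edge
correlations ≈ 0.2–0.3 after noise, typical of resting-state edges).
Atlas emulation: regions in fixed frontal/temporal/limbic/occipital/parietal
proportions 48:32:28:20:20 scaled per hemisphere by largest remainder
(the insula label is supported but not produced by default); per-ROI
thickness from a clipped normal centred at 2.4 mm with sd 0.25 mm,
matching the hemisphere-mean scale of anatomical parcellations.

What the generator does **not** emulate: hemodynamic autocorrelation and
low-pass character of BOLD, motion and physiological artifacts,
inter-subject anatomical variability, distance-dependent connection
strength, and negative correlations. Passing tests therefore demonstrate
that the pipeline recovers planted laminar structure and controls false
positives under an idealized noise model — not that any specific laminar
finding in real data is correct.

## 4. Statistics

Layer comparisons (`compare_layers()`) are classical one-way ANOVAs over
the D layers with participants as replicates, on the AUC of each measure.
Global scope corrects across measures with Benjamini–Hochberg at α = 0.05;
nodal scope corrects across the nodes of one measure with Holm at α = 0.01.
Holm is a family-wise-error (step-down) procedure rather than an FDR one;
it is implemented as the named method. For multilayer and between-layer
networks only nodal quantities are compared, each ROI's D depth-copies
forming the groups — global supra-matrix measures mix every layer and are
uninterpretable as layer contrasts. Each result carries the peak layer
(argmax of layer-mean AUC); ties break to the most superficial layer, a
fixed rule where none is prescribed. Degenerate inputs follow explicit
conventions (all-identical observations: F = 0, p = 1; zero within-group
variance with unequal means: p = 0 sentinel with a warning). ANOVA
normality and variance-homogeneity caveats apply as usual and are the
user's to weigh; the package does not gate on them.

The cortical-thickness confound check (`thickness_confound_test()`) runs a
pooled-variance two-sample t test of ROI thickness, significant versus
nonsignificant nodes, only for measures with strictly more than 10
significant nodes; smaller sets are reported as skipped rather than tested.

Edge dispersion (`edge_dispersion()`) operates on the raw Fisher-z supra
matrices — before normalization and thresholding, which would distort
across-participant standard deviations. The selected fraction is
`floor(0.05 · E)` edges with index-order tie-breaking. Per-layer totals
assign within-layer blocks fully and split between-layer blocks half to
each participating layer; this is the only aggregation under which the
per-layer totals, like the block percentages, sum to 100%, and it is
flagged as an interpretation rather than a prescribed rule.

## 5. Problem sizes and determinism

Every stochastic routine is a pure function of an explicit integer seed
(generators, Louvain restarts, rewiring nulls), and sub-seeds are derived
deterministically, so cohorts, pipelines and whole `run_pipeline()` outputs
are bit-reproducible. The validation suites run at deliberately scaled-down
sizes chosen to exercise every code path many times over: exhaustive oracle
comparison on all labeled connected graphs of up to 5 nodes plus seeded
random weighted graphs on 6–7 nodes; Monte-Carlo calibration and recovery
on 20 cohorts of 10 participants × 40 ROIs × 3 depths × 400 time points;
and full-parcellation construction checks at 148 ROIs × 5 depths. The
148-ROI atlas with ~2,000 time points and 30 participants runs through the
same code paths unchanged; only the measure suite's Louvain restarts and
betweenness at 740 nodes × 20 densities are materially expensive there.

## 6. Known limitations

* The latent-factor null is idealized; real resting-state noise is
  autocorrelated and non-stationary, and the type-I calibration result
  should not be read as a guarantee for real data.
* Normalization by the maximum weight couples all weights to a single
  extreme statistic; alternative schemes (e.g. rank or z normalization)
  may change within-/between-layer density profiles and are not explored.
* The multilayer matrix is treated as one static graph; no interlayer
  coupling parameter or multislice community detection is provided.
* Negative-weight network analysis is excluded by design.
* Louvain is a heuristic; the restart scheme bounds but does not guarantee
  the maximum-modularity partition (the test suite checks the bound against
  exhaustive enumeration on small graphs).
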