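# laminarnet

Laminar multilayer functional connectomics in R: build and compare
depth-resolved functional brain networks from ROI × cortical-depth fMRI time
series.

High-resolution (e.g. 7-T) fMRI can sample the BOLD signal at several
cortical depths between the white-matter and pial surfaces, giving each
atlas region not one but D time series. `laminarnet` implements the
network-analysis side of that experiment for researchers in laminar fMRI and
brain connectomics: given per-participant time-series tables (rows = time
points, columns = ROI × depth channels) and an atlas table, it constructs
depth-resolved functional networks, derives threshold-free graph-measure
profiles per depth, and tests which measures differ across cortical depths.

## The analysis

For each participant the conditioned channels (linear detrend, zero-phase
second-order Butterworth band-pass 0.01–0.1 Hz) are correlated and
Fisher-z-transformed, `z = arctanh(r)`, under two parallel pipelines:

* **layer-by-layer** — one R × R matrix per depth from the R channels of
  that depth (R(R−1)/2 unique pairs each; 10,878 for a 148-ROI
  parcellation);
* **multilayer** — a single (R·D) × (R·D) supra-adjacency matrix over all
  within- and between-depth pairs in depth-major node order (740 nodes and
  273,430 pairs at 148 ROIs × 5 depths). Its diagonal blocks after
  thresholding are the **within-layer** matrices; zeroing those blocks gives
  the **between-layer** matrix.

Matrices are normalized (negative weights zeroed, rescaled to max 1) and
proportionally thresholded to graph densities 2%–40% in 2% steps. Every
measure of the weighted graph-theory suite — density, degree, strength,
largest cluster size; characteristic path length, global efficiency, radius,
diameter; betweenness and eigenvector centrality; modularity, transitivity,
clustering, local efficiency, participation; assortativity; small-world σ —
is evaluated along the grid and summarized threshold-free by its trapezoidal
area under the curve (AUC). Layer differences are tested with one-way ANOVAs
on the AUCs (participants as replicates), Benjamini–Hochberg correction
across global measures (α = 0.05) and Holm correction across nodes within a
measure (α = 0.01), with each measure's peak layer reported. Edge
consistency/variability selects the 5% of multilayer edges with the
lowest/highest standard deviation across participants and tabulates them by
layer block; matrix-generation methods are compared per layer with cosine
similarity of upper-triangular weight vectors.

Because the corresponding imaging data are not publicly deposited, the
package ships a first-class synthetic generator: a latent-factor
linear-Gaussian model with planted, depth-nested ROI graphs whose density
follows a configurable laminar gradient, superficial-ward signal leakage
emulating the draining-vein bias, and additive channel noise. All planted
structure is known, so recovery and calibration are testable end to end.

## Worked example

```r
library(laminarnet)

atlas  <- generate_atlas(40, seed = 1)
cohort <- generate_cohort(atlas, n_participants = 10, n_depths = 3,
                          n_timepoints = 400, tr_seconds = 2.8,
                          effect = effect_spec(density_gradient = 0.5),
                          seed = 42)
cohort <- lapply(cohort, detrend_bandpass)

tab <- cohort_auc_table(cohort, "within_layer",
                        global_measures = c("mean_strength", "mean_degree"))
compare_layers(tab, "global")
#>         measure  scope node        F            p peak_layer   p_adjusted significant
#> 1 mean_strength global   NA 306.7142 2.729348e-19          1 5.458695e-19        TRUE
#> 2   mean_degree global   NA 232.2835 9.706093e-18          1 9.706093e-18        TRUE
```

The planted superficial density gradient is recovered: mean strength and
degree AUC differ strongly across the three depths (one-way ANOVA,
Benjamini–Hochberg-corrected p ≪ 0.05) and both peak in layer 1, the most
superficial depth, as the generator planted.

The whole analysis can also be driven by one call (or from a shell via
`inst/cli/laminarnet.R`):

```r
run_pipeline(list(out_dir = "out"), seed = 42)
```

which writes AUC tables, layer statistics, edge-dispersion and
method-similarity tables plus a provenance log (config hash, seeds,
versions) as TSV/JSON.

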