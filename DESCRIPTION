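Package: laminarnet
Title: Laminar Multilayer Functional Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses depth-resolved (laminar) functional brain
    networks from ROI-by-cortical-depth fMRI time series. Provides a
    synthetic cohort generator with planted laminar connectivity structure,
    zero-phase Butterworth band-pass conditioning, Fisher-z correlation
    matrices for layer-by-layer and multilayer (supra-adjacency) pipelines,
    proportional thresholding over a graph-density grid, a weighted
    graph-measure suite with threshold-free area-under-curve summaries,
    edge consistency/variability fingerprinting, cosine matrix similarity,
    and layer-wise ANOVA with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
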