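Package: TrackPheno
Title: Behavioral Phenotyping of Single-Cell Migration Tracks from
    Intravital Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies the migratory behavior of individually tracked
    cells from time-lapse (intravital) microscopy. Tracking exports from
    Imaris, TrackMate, MTrackJ and ManualTracking are parsed into a
    canonical track table; per-track multivariate kinetic time series
    (speed, displacement, persistence, invasion velocity relative to a
    tumor-edge surface) are interpolated to a uniform grid, cropped to a
    common length, compressed by principal components, and compared with
    multivariate dynamic time warping. The resulting cross-distance
    matrix is embedded with UMAP and clustered with k-means to yield
    behavioral clusters, which can be characterized against tumor
    microenvironment composition at single-cell neighborhood scale
    (nearest-neighbor densities, radius counts, proximity to vessels and
    macrophages) and at tissue-region scale (per-region cluster
    frequencies with per-mouse normalization). A persistent-random-walk
    simulator with planted behavioral archetypes provides a fully
    synthetic test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    uwot,
    FNN,
    cluster,
    lme4,
    lmerTest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    emmeans,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
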