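# TrackPheno

Behavioral phenotyping of single-cell migration tracks from time-lapse
(intravital) microscopy.

Intravital imaging of tumors yields hundreds of single-cell tracks per
imaging position. Classical readouts compress each track into one number
(mean speed, net displacement) and miss cells that move equally fast in
opposite directions — invading away from the tumor edge versus
retreating back toward it. TrackPheno classifies cells by the *shape* of
their whole multivariate kinetic time series instead, and then asks
whether the resulting behavioral clusters sit in distinctive tumor
microenvironments (TME). It is written for researchers analyzing
tracking exports from Imaris, TrackMate, MTrackJ or ManualTracking.

## Method

For each track on a uniform time grid (spacing *dt*, positions
*p*<sub>0</sub>…*p*<sub>i</sub>) the per-timepoint features are

- speed<sub>i</sub> = ‖*p*<sub>i</sub> − *p*<sub>i−1</sub>‖ / *dt*
- disp_d<sub>i</sub> = ‖*p*<sub>i</sub> − *p*<sub>0</sub>‖ (net
  displacement), disp2<sub>i</sub> = disp_d<sub>i</sub>²
- disp_l<sub>i</sub> = Σ<sub>j≤i</sub> ‖*p*<sub>j</sub> −
  *p*<sub>j−1</sub>‖ (path length)
- persistence<sub>i</sub> = disp_d<sub>i</sub> / disp_l<sub>i</sub> ∈
  [0, 1]
- invasion<sub>i</sub> = (d<sub>i</sub> − d<sub>i−1</sub>) / *dt*, the
  velocity relative to a tumor-edge surface (d = distance to the edge;
  positive = moving away into healthy tissue)

Missing frames are filled by linear interpolation, tracks are cropped to
the minimal common length, features are standardized and compressed by
PCA (keeping the fewest components explaining ≥ 90% of variance). The
pairwise dissimilarity between tracks is **dependent multivariate
dynamic time warping** (one warping path across all PC dimensions,
Euclidean local cost, `symmetric2` step pattern), giving a cross-distance
matrix that is embedded in 2D with UMAP and partitioned with k-means.
Clusters are characterized by per-cluster feature means (min–max
rescaled for heatmaps) with one-way ANOVA per feature.

Two TME analyses attach context to the clusters:

- **single-cell neighborhood scale** — mean distance to the k nearest
  tumor cells, counts of microenvironment objects (e.g. SR101+ glia,
  CD20r+ macrophages) within a 30 µm radius, minimum distance to each
  component, and proximity classification (≤ 15 µm for surface-derived
  objects, ≤ 3 µm for vessel spots), integrated either *upstream* (as
  clustering inputs) or *downstream* (compared across clusters, with
  mouse/TME-class random effects);
- **tissue-region scale** — per-position behavioral-cluster frequencies
  across externally defined TME regions (Void, TAMM/Oligo,
  TAMM/vascularized, …), z-scored per mouse, compared by ANOVA + Tukey
  HSD.

A persistent-biased-random-walk simulator with seven planted archetypes
(invading, slow invading, retreating, slow retreating, erratic, slow,
static) generates fully synthetic scenes — tracks, a planar tumor edge,
vessel polylines, component point clouds, region partitions — and writes
fixture files in every supported export dialect.

## Worked example

```r
library(TrackPheno)

sc  <- sceneConfig(archetypePresets("easy", n_tracks = 40),
                   n_timepoints = 9, seed = 7)
sim <- simulateTracks(sc)
sim$table
#> TrackTable: 280 tracks, 2270 rows, 3D
#>   mice: 1  positions: 1
#>   t range: 0.000..2.667 hours
#>   dist_to_edge: present

tracks <- cropCommonLength(interpolateToGrid(sim$table, dt = 1/3))
#> cropped all tracks to L = 7 timepoints
tensor <- computeKineticFeatures(tracks)
pcs    <- scaleAndPCA(tensor, var_threshold = 0.90)
pcs
#> PCSeries: 280 tracks, 4 PCs retained (cumulative variance 97.7% >= threshold 90%)

D   <- crossDistance(pcs)
res <- embedAndCluster(D, k = 7, seed = 7)
res
#> ClusterResult: 280 tracks, k = 7
#>   cluster sizes: 37, 37, 46, 43, 36, 41, 40
res <- characterizeClusters(res, summarizeTrackFeatures(tensor))
```

The mean invasion velocity per cluster identifies the invading (largest
positive, here +10.8 µm/h, cluster 6) and retreating (most negative,
−10.1 µm/h, cluster 5) phenotypes; the per-feature ANOVA confirms the
clusters differ (p ≈ 4e-150):

```r
s <- clusterSummary(res)
s[s$feature == "mean_invasion", c("cluster", "mean", "rescaled")]
#>   cluster     mean rescaled
#>         6  10.8298    1.000
#>         4   3.4961    0.649
#>         7  -0.0202    0.481
#>         2  -0.0868    0.478
#>         1  -0.1357    0.475
#>         3  -4.2190    0.280
#>         5 -10.0659    0.000
```

Against the simulator's planted archetypes this run reaches an adjusted
Rand index of 0.844. `writeBackprojection(res, tracks, "bp.csv")`
re-attaches the labels to every original timepoint for visualization in
the source imaging software, and `runPipeline()` drives the same chain
(plus the TME modules) from a single config list or YAML file, writing
every artifact with an md5 manifest.

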