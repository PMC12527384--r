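---
title: "Behavioral phenotyping of cell tracks: models, parameters and design choices"
author: "TrackPheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral phenotyping of cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrackPheno)
```

## The problem and the model

Time-lapse microscopy of tumors in living animals produces per-cell
tracks: sequences of 3D positions (2D for projected data), often with a
per-timepoint distance to a manually rendered tumor-edge surface.
Single-number summaries cannot distinguish a cell invading away from
the tumor edge from one retreating toward it at the same speed, nor a
persistent mover from an erratic one with the same displacement.
TrackPheno therefore treats each track as a *multivariate time series*
of kinetic features and classifies cells by time-series similarity.

The chain is: linear interpolation onto a uniform grid → cropping to
the minimal common track length → per-timepoint features (speed,
squared displacement, net displacement, path length, persistence,
invasion velocity) → per-feature standardization and PCA → dependent
multivariate dynamic time warping (DTW) between the per-track PC series
→ UMAP embedding of the cross-distance matrix → k-means clustering →
per-cluster characterization, with optional microenvironment analyses
at single-cell-neighborhood and tissue-region scales.

Assumptions worth making explicit:

- **Linear interpolation** assumes motion is approximately linear
  between observed frames; it is exact for affine-in-time motion (a
  tested invariant) and a deliberate underestimate of curvature for
  anything else. No extrapolation is ever performed beyond a track's
  observed span.
- **Cropping** takes the *first* L grid points of each track, L being
  the minimal track length, so all tracks are aligned at their own
  start. A sliding-window alternative would mix behavioral phases; the
  track start is the natural anchor for invasion analysis. Note that L
  is data-dependent: with a 20-min frame interval (`dt = 1/3` h) a
  9-frame acquisition cropped at L = 8–9 covers roughly a 2.3–2.7 h
  observation window.
- **Dependent DTW** aligns all feature dimensions with one warping
  path, i.e. it assumes the features of one cell are time-shifted
  *together* (a cell that pauses, pauses in all features). The
  independent per-dimension variant is not offered because the PC
  series that feed the DTW are already linear mixtures of all features.
- The **tumor edge** enters only through the exported distance column;
  its geometry is never reconstructed.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `dt` | 1/3 | h | 20-min frame interval typical for intravital tumor imaging |
| `var_threshold` | 0.90 | fraction | retain the smallest PC set explaining ≥ 90% of pooled variance |
| DTW `step` | `symmetric2` | — | standard symmetric pattern; diagonal weighted twice so warped and unwarped paths are comparable |
| DTW `window` | none | frames | a Sakoe–Chiba band only restricts warping; it can never lower a distance (tested invariant) |
| `k` | user choice | clusters | no automatic selection; `silhouetteDiagnostic()` reports average widths but never picks |
| UMAP `n_neighbors`, `min_dist` | 15, 0.1 | — | the uwot defaults, documented as conventions, not derived quantities |
| spatial `radius` | 30 | µm | conventional neighborhood radius for object counts |
| proximity threshold | 15 / 3 | µm | surface-derived objects already extend toward the cell (15 µm); centroid spots need a stricter cutoff (3 µm); both boundaries inclusive |
| kNN density | k = 10 (and 3) | cells | 10-neighbor mean distance as cell-density proxy; 3-neighbor as a more local variant |
| z-scoring | per (mouse, cluster) | — | removes inter-mouse offsets before region comparisons; sample (n−1) sd |

Seeds default to 42, are taken explicitly by every stochastic function,
and are recorded in the returned objects; identical inputs and seeds
reproduce byte-identical artifacts (the pipeline manifest proves it).

## Design choices where the design was genuinely open

- **Persistence direction.** The directionality ratio is defined as net
  displacement over path length (`disp_d / disp_l ∈ [0, 1]`), the
  conventional movement-efficiency ratio; the reciprocal is not
  exposed. Note two degenerate values: persistence is defined as 0 for
  a zero-length path (static cell), and equals exactly 1 at the first
  moving timepoint (one step: net = path). Consequently the per-track
  summary `persistence_range` is identically 1 for any moving track and
  carries no information — the characterization step then reports its
  ANOVA as undefined with a warning rather than a spurious p-value.
- **First-timepoint values.** `speed_0 = 0` and `invasion_0 = 0` (not
  NA) keep the tensor gap-free; a backward difference defines both.
- **disp2** is the squared distance from the track start (pairing it
  with `disp_d`), not a per-step quantity.
- **Cluster labels** are integers 1..k, following R factor conventions.
- **Clustering space.** k-means runs on the 2D UMAP embedding by
  default; `method = "pam"` clusters the DTW distance matrix directly
  for users who distrust the embedding's distortions. Both are exposed
  because either is defensible; the planted-archetype tests exercise
  both.
- **Feature standardization before PCA** is mandatory: features mix µm,
  µm² and unitless ratios, and an unstandardized PCA is dominated by
  the largest unit.
- **Imaris multi-file joins** are strict inner joins on
  (TrackID, Time); any orphan key aborts with a listing, because silent
  row loss in a join is the classic source of irreproducible track
  counts.
- **Region granularity.** Regions arrive as per-position labels (each
  imaged position is matched to one region), with an optional per-cell
  table taking precedence; region discovery itself is external input
  and never recomputed.
- **TME components are a static snapshot**: moving cells are measured
  against fixed point clouds at every timepoint, and track-level values
  are time means. Surface-derived objects are represented by boundary
  sample points, so distance-to-surface is approximated to the sampling
  density.
- **No cross-feature multiplicity correction** is applied to the
  per-feature ANOVA p-values (Tukey adjusts within its own family
  only); users comparing many features should correct downstream.

## What the simulator emulates — and what it does not

`simulateTracks()` draws persistent biased random walks: per frame the
direction is `normalize(p·prev + (1−p)·u + b·ê_x)` with `u` uniform on
the unit sphere, persistence `p ∈ [0, 1]`, edge drift `b ∈ [−1, 1]`
(positive = away from the tumor), and Gamma-distributed step lengths
with archetype-specific means. The tumor edge is the plane x = 0, so
`dist_to_edge = max(x, 0)` and drift maps directly onto the invasion
feature; deterministic limits (`p = 1, b = 1`, no noise → perfectly
straight, persistence ≡ 1) are analytically checkable and tested.
Seven archetypes named by the field's motility vocabulary (invading,
slow invading, retreating, slow retreating, erratic, slow, static) come
in an "easy" strongly separated regime and a "hard" low-contrast one.
Scenes add frame dropout, vessel polylines (optionally laid along the
invading drift axis through invading-track start sites, planting
vascular proximity), Poisson component clouds with optional enrichment
near a named archetype, and per-position region labels with optional
archetype-mixture tilts.

This emulates the *structure* of the target data — archetype mixtures,
missing frames, edge-referenced motion, static vessel snapshots,
region-stratified positions — not its biology: there is no
Ornstein–Uhlenbeck velocity memory, no curved tumor edge, no imaging
noise or segmentation error, no cell division or track fragmentation.
Passing the planted-truth tests therefore shows the pipeline recovers
structure it can represent, not that any particular biological dataset
will separate as cleanly.

## Numerical choices

- Time-grid uniformity is asserted to 1e-9; fixture writers emit 17
  significant digits so dialect round trips hold to 1e-9.
- DTW is implemented in C++ with a two-row rolling buffer; the test
  suite pins it to an independent recursive path-minimization oracle at
  1e-9 over random multivariate pairs, and to hand-computable cases
  (identical series → 0, length-1 series → the single cell cost).
- Constant features are dropped before PCA (they have no z-score);
  a feature constant *across clusters* min–max rescales to 0.
- ANOVA with zero between- and within-group variance returns a missing
  p-value with a warning rather than 0/0.
- When fewer than k neighbors exist, the kNN density is missing, never
  padded; upstream integration refuses features containing missing
  values since the tensor must stay gap-free.
- Decimal commas in numeric cells abort parsing with a row reference
  (European spreadsheet exports are a known hazard).

## Problem sizes used in the checks

The packaged tests and the acceptance script run on simulated scenes
sized for a desk machine: 7 archetypes × 40 tracks × 9 timepoints
(280 tracks) for pipeline-level recovery, 20-replicate batches of
7 × 20-track scenes for the planted vascular-tropism check, 3 mice × 6
positions with 10 tracks per archetype for region enrichment, 200-fold
null replicates for calibration, and 1000-point scenes for the spatial
brute-force comparisons. These sizes were chosen to make Monte-Carlo
margins comfortable at desk scale; nothing in the implementation
depends on them.

## Known limitations

- UMAP + k-means is a stochastic pipeline: with a fixed seed it is
  exactly reproducible, but cluster recovery of equally sized planted
  groups varies across scene realizations (adjusted Rand index roughly
  0.6–0.9 on the easy regime at 280 tracks). The distance matrix, not
  the embedding, is the stable object; PAM on the distance matrix is
  the conservative alternative.
- Cropping to the minimal common length discards data from long tracks;
  heavily fragmented tracking lowers L for everyone. Filter very short
  tracks before cropping (the crop errors below L = 3).
- The mixed-effects comparison is a thin contract over lme4/lmerTest:
  non-convergence and singular fits are reported, and no fallback to a
  fixed-effects ANOVA ever happens silently.
- 2D data are handled as z = 0; all geometry is written for 3D and
  degrades exactly, but features mixing 2D morphology with 3D kinetics
  should be selected deliberately.
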