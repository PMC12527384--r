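# Small-scale phenotyping: single-cell spatial statistics against static
# TME component point clouds, and their integration with behavioral
# clusters (upstream of clustering, or downstream against existing
# clusters).

.cellMatrix <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")])
    storage.mode(m) <- "double"
    m
}

#' Mean distance to the k nearest neighboring cells
#'
#' Tumor-cell density proxy: for each cell the mean Euclidean distance
#' to its k nearest other cells at the same timepoint. Cells with fewer
#' than k neighbors available get NA (missing, not padded).
#'
#' @param cells numeric matrix (n x 2 or n x 3) of coordinates, µm.
#' @param k neighbor count (k = 10 is the conventional density readout;
#'   k = 3 a more local one).
#' @return numeric vector of length n.
#' @export
knnMeanDistance <- function(cells, k) {
    stopifnot(k >= 1)
    cells <- as.matrix(cells)
    if (ncol(cells) == 2L) cells <- cbind(cells, 0)
    n <- nrow(cells)
    if (n - 1L < k) return(rep(NA_real_, n))
    nn <- FNN::get.knn(cells, k = k)
    rowMeans(nn$nn.dist)
}

#' Count component objects within a radius
#'
#' Number of component points at distance <= `radius` (boundary
#' inclusive) from each cell. An empty component yields all-zero counts
#' with a warning.
#'
#' @param cells numeric matrix of cell coordinates (n x 2 or n x 3), µm.
#' @param component a [TMEComponentSet-class].
#' @param radius search radius in µm; 30 µm is the conventional
#'   neighborhood radius for these counts.
#' @return integer vector of length n.
#' @export
countWithinRadius <- function(cells, component, radius = 30) {
    stopifnot(is(component, "TMEComponentSet"), radius > 0)
    cells <- as.matrix(cells)
    if (ncol(cells) == 2L) cells <- cbind(cells, 0)
    pts <- componentPoints(component)
    if (nrow(pts) == 0L) {
        warning("component '", component@componentName,
                "' is empty; counts are 0", call. = FALSE)
        return(integer(nrow(cells)))
    }
    r2 <- radius^2
    vapply(seq_len(nrow(cells)), function(i) {
        d2 <- (pts[, 1] - cells[i, 1])^2 + (pts[, 2] - cells[i, 2])^2 +
              (pts[, 3] - cells[i, 3])^2
        sum(d2 <= r2 + 1e-12)
    }, integer(1))
}

#' Minimum distance to a component
#'
#' Euclidean distance from each cell to the nearest component point.
#' For surface-derived components the point cloud samples the surface
#' boundary, so this approximates distance-to-surface up to the sampling
#' density.
#'
#' @inheritParams countWithinRadius
#' @return numeric vector of length n (NA with a warning when the
#'   component is empty).
#' @export
minComponentDistance <- function(cells, component) {
    stopifnot(is(component, "TMEComponentSet"))
    cells <- as.matrix(cells)
    if (ncol(cells) == 2L) cells <- cbind(cells, 0)
    pts <- componentPoints(component)
    if (nrow(pts) == 0L) {
        warning("component '", component@componentName,
                "' is empty; min distances are NA", call. = FALSE)
        return(rep(NA_real_, nrow(cells)))
    }
    as.numeric(FNN::get.knnx(pts, cells, k = 1)$nn.dist)
}

#' Classify cells as close to a component
#'
#' Proximity rule: close iff `min_dist <= threshold` (inclusive). The
#' default threshold depends on how the reference objects were rendered:
#' 15 µm for surface-derived components (the surface boundary already
#' extends toward the cell) versus 3 µm for centroid-based spots, where
#' a stricter cutoff compensates for the missing object extent.
#'
#' @param min_dist per-cell minimum distances (µm); NA is never close.
#' @param object_kind "surface_sample" or "spot".
#' @param threshold override in µm, or NULL for the kind's default.
#' @return logical vector.
#' @export
classifyProximity <- function(min_dist,
                              object_kind = c("surface_sample", "spot"),
                              threshold = NULL) {
    object_kind <- match.arg(object_kind)
    if (is.null(threshold)) {
        threshold <- if (object_kind == "surface_sample") 15 else 3
    }
    !is.na(min_dist) & min_dist <= threshold
}

#' Per-timepoint spatial feature table
#'
#' For every (position, timepoint) scene the tumor cells present are
#' measured against each other (`dist_<k>_neigh`) and against every TME
#' component cloud registered for that position (`n_<comp>` within
#' `radius`, `min_<comp>`). Components are static snapshots; the moving
#' cells are measured against them at each timepoint.
#'
#' @param table a [TrackTable-class] (ideally the interpolated, cropped
#'   one, so the rows align with the feature tensor).
#' @param components list of [TMEComponentSet-class]; a component whose
#'   `positionId` is NA applies to every position.
#' @param radius radius for the counts, µm.
#' @param k_neigh integer vector of neighbor counts for the density
#'   features.
#' @return data.frame keyed by (mouse_id, position_id, track_id, t) with
#'   one column per spatial feature.
#' @export
computeSpatialFeatures <- function(table, components, radius = 30,
                                   k_neigh = c(3, 10)) {
    stopifnot(is(table, "TrackTable"), is.list(components))
    df <- trackData(table)
    compNames <- vapply(components, function(cp) cp@componentName,
                        character(1))
    if (anyDuplicated(paste(compNames, vapply(components, function(cp)
        cp@positionId, character(1))))) {
        stop("duplicate component name within a position", call. = FALSE)
    }
    key <- paste(df$mouse_id, df$position_id, df$t, sep = "\r")
    out <- df[, c("mouse_id", "position_id", "track_id", "t")]
    for (k in k_neigh) out[[paste0("dist_", k, "_neigh")]] <- NA_real_
    for (nm in unique(compNames)) {
        out[[paste0("n_", nm)]] <- NA_integer_
        out[[paste0("min_", nm)]] <- NA_real_
    }
    for (scene in unique(key)) {
        idx <- which(key == scene)
        cells <- .cellMatrix(df[idx, ])
        for (k in k_neigh) {
            out[idx, paste0("dist_", k, "_neigh")] <-
                knnMeanDistance(cells, k)
        }
        pos <- df$position_id[idx[1]]
        for (cp in components) {
            if (!is.na(cp@positionId) && cp@positionId != pos) next
            nm <- cp@componentName
            out[idx, paste0("n_", nm)] <-
                countWithinRadius(cells, cp, radius)
            out[idx, paste0("min_", nm)] <-
                minComponentDistance(cells, cp)
        }
    }
    out
}

#' Integrate spatial features with the behavioral analysis
#'
#' Two integration routes:
#' \describe{
#'   \item{upstream}{spatial features become additional input variables
#'     for the clustering: selected per-timepoint columns of `spatial`
#'     are appended to the [FeatureTensor-class] before
#'     [scaleAndPCA()]. Requires full per-timepoint coverage of the
#'     tensor's tracks and grid (per-track-only features cannot be
#'     time-aligned and abort). With zero selected features the tensor
#'     is returned unchanged.}
#'   \item{downstream}{previously defined behavioral clusters are
#'     correlated with spatial features: per-track time means are
#'     summarized per cluster (means + one-way ANOVA per feature), the
#'     per-position percentage of cells close to each component is
#'     computed, and cluster differences in those percentages are tested
#'     with a mixed model including mouse (and, when region labels are
#'     supplied, TME class) as random effects.}
#' }
#'
#' @param mode "upstream" or "downstream".
#' @param spatial table from [computeSpatialFeatures()].
#' @param tensor (upstream) the [FeatureTensor-class] to augment.
#' @param features (upstream) character vector of spatial columns to
#'   append; default all feature columns of `spatial`.
#' @param result (downstream) a [ClusterResult-class].
#' @param table (downstream) the [TrackTable-class] carrying
#'   mouse/position metadata.
#' @param components (downstream) the component list, used for proximity
#'   thresholds via each component's `objectKind`.
#' @param regions (downstream, optional) data.frame (mouse_id,
#'   position_id, region_label) adding a TME-class random effect.
#' @return upstream: an augmented [FeatureTensor-class]. downstream: a
#'   list with `track_features`, `cluster_summary`, `proximity` (per
#'   position x cluster x component percentages) and `proximity_tests`.
#' @export
integrateSpatial <- function(mode = c("upstream", "downstream"), spatial,
                             tensor = NULL, features = NULL,
                             result = NULL, table = NULL,
                             components = NULL, regions = NULL) {
    mode <- match.arg(mode)
    keyCols <- c("mouse_id", "position_id", "track_id", "t")
    featCols <- setdiff(names(spatial), keyCols)
    if (mode == "upstream") {
        stopifnot(is(tensor, "FeatureTensor"))
        if (is.null(features)) features <- featCols
        if (length(features) == 0L) return(tensor)
        bad <- setdiff(features, featCols)
        if (length(bad)) {
            stop("unknown spatial features: ",
                 paste(bad, collapse = ", "), call. = FALSE)
        }
        gid <- paste(spatial$mouse_id, spatial$position_id,
                     spatial$track_id, sep = ".")
        # tracks start at their own t0; align on time since track start
        t0 <- stats::ave(spatial$t, gid, FUN = min)
        skey <- paste(gid, signif(spatial$t - t0, 12), sep = "\r")
        d <- dim(tensor@values)
        want <- paste(rep(tensor@trackIndex, times = d[2]),
                      signif(rep(tensor@timeGrid, each = d[1]), 12),
                      sep = "\r")
        hit <- match(want, skey)
        if (anyNA(hit)) {
            stop("spatial features do not cover every (track, timepoint) ",
                 "of the tensor; time alignment impossible (are they ",
                 "per-track summaries?)", call. = FALSE)
        }
        arr <- array(NA_real_, dim = c(d[1], d[2], d[3] + length(features)),
                     dimnames = list(tensor@trackIndex, NULL,
                                     c(tensor@featureNames, features)))
        arr[, , seq_len(d[3])] <- tensor@values
        for (j in seq_along(features)) {
            v <- spatial[[features[j]]][hit]
            if (anyNA(v)) {
                stop("spatial feature '", features[j], "' has missing ",
                     "values (e.g. too few neighbors); it cannot enter ",
                     "the gap-free tensor", call. = FALSE)
            }
            arr[, , d[3] + j] <- matrix(v, d[1], d[2])
        }
        new("FeatureTensor", values = arr, trackIndex = tensor@trackIndex,
            timeGrid = tensor@timeGrid,
            featureNames = c(tensor@featureNames, features),
            provenance = c(tensor@provenance,
                           setNames(rep("passthrough", length(features)),
                                    features)))
    } else {
        stopifnot(is(result, "ClusterResult"), is(table, "TrackTable"))
        gid <- paste(spatial$mouse_id, spatial$position_id,
                     spatial$track_id, sep = ".")
        agg <- aggregate(spatial[featCols], by = list(track = gid),
                         FUN = function(v) mean(v, na.rm = TRUE))
        lab <- clusterLabels(result)
        agg <- agg[agg$track %in% names(lab), , drop = FALSE]
        agg$cluster <- as.integer(lab[agg$track])
        meta <- unique(trackData(table)[, c("mouse_id", "position_id",
                                            "track_id")])
        meta$track <- paste(meta$mouse_id, meta$position_id,
                            meta$track_id, sep = ".")
        agg <- merge(agg, meta, by = "track")
        # per-cluster feature summary with ANOVA across clusters
        sm <- list()
        for (f in featCols) {
            v <- agg[[f]]
            ok <- is.finite(v)
            if (!any(ok)) next
            means <- tapply(v[ok], agg$cluster[ok], mean)
            rng <- max(means) - min(means)
            p <- if (length(unique(agg$cluster[ok])) >= 2) {
                oneWayAnova(v[ok], agg$cluster[ok])$p
            } else NA_real_
            sm[[f]] <- data.frame(
                cluster = as.integer(names(means)), feature = f,
                mean = as.numeric(means),
                rescaled = if (rng > 0) {
                    (as.numeric(means) - min(means)) / rng
                } else 0,
                anova_p = p, stringsAsFactors = FALSE)
        }
        clusterSummary <- do.call(rbind, c(sm, make.row.names = FALSE))
        # percentage of close cells per position x cluster x component
        proximity <- NULL
        tests <- list()
        kinds <- setNames(
            vapply(components %||% list(), function(cp) cp@objectKind,
                   character(1)),
            vapply(components %||% list(), function(cp) cp@componentName,
                   character(1)))
        for (nm in unique(names(kinds))) {
            col <- paste0("min_", nm)
            if (!col %in% names(agg)) next
            agg[[paste0("close_", nm)]] <-
                classifyProximity(agg[[col]], kinds[[nm]])
            pct <- aggregate(
                agg[[paste0("close_", nm)]],
                by = list(mouse_id = agg$mouse_id,
                          position_id = agg$position_id,
                          cluster = agg$cluster),
                FUN = function(v) 100 * mean(v))
            names(pct)[4] <- "pct_close"
            pct$component <- nm
            proximity <- rbind(proximity, pct)
            mm <- pct
            if (!is.null(regions)) {
                mm <- merge(mm, regions, by = c("mouse_id", "position_id"))
            }
            rand <- c("mouse_id",
                      if (!is.null(regions)) "region_label")
            tests[[nm]] <- if (length(unique(mm$mouse_id)) >= 2) {
                mixedModelCompare(mm, "pct_close", "cluster",
                                  random = rand)
            } else {
                list(fixed_p = NA_real_, converged = FALSE,
                     message = "single mouse; mixed model not identifiable")
            }
        }
        list(track_features = agg, cluster_summary = clusterSummary,
             proximity = proximity, proximity_tests = tests)
    }
}
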