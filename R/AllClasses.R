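#' Canonical per-timepoint track table
#'
#' Long-format container for tracked cells: one row per (mouse, position,
#' track, timepoint). Coordinates are in micrometers and time in hours;
#' every reader converts units once at the boundary. 2D data are stored
#' with `z = 0`. The optional `dist_to_edge` column holds the distance to
#' a tumor-edge reference surface (µm, non-negative); additional numeric
#' columns (e.g. morphology exported by the tracking software) are listed
#' in `extraFeatures` and passed through untouched.
#'
#' @slot data data.frame with columns `mouse_id`, `position_id`,
#'   `track_id` (character), `t` (hours), `x`, `y`, `z` (µm),
#'   `dist_to_edge` (µm or NA), plus any extra feature columns. Rows are
#'   ordered by (mouse, position, track, t).
#' @slot timeUnit single string, always "hours".
#' @slot coordUnit single string, always "micron".
#' @slot dimensionality integer, 2 or 3.
#' @slot extraFeatures character vector naming passthrough feature columns.
#'
#' @seealso [TrackTable()] for the constructor, [readImarisExport()],
#'   [readTrackMateSpots()], [readFijiManual()] for parsers.
#' @exportClass TrackTable
setClass("TrackTable",
    representation(
        data = "data.frame",
        timeUnit = "character",
        coordUnit = "character",
        dimensionality = "integer",
        extraFeatures = "character"
    ),
    prototype(
        timeUnit = "hours", coordUnit = "micron",
        dimensionality = 3L, extraFeatures = character()
    )
)

.trackKey <- function(df) {
    paste(df$mouse_id, df$position_id, df$track_id, sep = "\r")
}

setValidity("TrackTable", function(object) {
    df <- object@data
    req <- c("mouse_id", "position_id", "track_id", "t", "x", "y", "z",
             "dist_to_edge")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    }
    if (!object@dimensionality %in% c(2L, 3L)) {
        return("dimensionality must be 2 or 3")
    }
    if (nrow(df) == 0L) return(TRUE)
    if (!all(is.finite(df$t)) || !all(is.finite(df$x)) ||
        !all(is.finite(df$y)) || !all(is.finite(df$z))) {
        return("non-finite time or coordinates")
    }
    de <- df$dist_to_edge
    if (any(!is.na(de) & de < 0)) return("dist_to_edge must be >= 0")
    key <- paste(.trackKey(df), df$t, sep = "\r")
    if (anyDuplicated(key)) {
        return("duplicate (mouse, position, track, t) keys")
    }
    tk <- .trackKey(df)
    ord <- unlist(tapply(df$t, factor(tk, levels = unique(tk)),
                         function(v) all(diff(v) > 0)), use.names = FALSE)
    if (!all(ord)) return("t not strictly increasing within a track")
    n <- table(tk)
    if (any(n < 2L)) return("every track needs >= 2 timepoints")
    bad <- setdiff(object@extraFeatures, names(df))
    if (length(bad)) {
        return(paste("extraFeatures absent from data:",
                     paste(bad, collapse = ", ")))
    }
    TRUE
})

#' Construct a TrackTable
#'
#' Orders rows by (mouse, position, track, t), fills `z = 0` for 2D input
#' and a `dist_to_edge` column of NA when absent, and validates the
#' object.
#'
#' @param data data.frame with at least `mouse_id`, `position_id`,
#'   `track_id`, `t`, `x`, `y`; `z` and `dist_to_edge` optional.
#' @param extraFeatures character vector of passthrough feature column
#'   names present in `data`.
#' @return a validated [TrackTable-class] object.
#' @examples
#' df <- data.frame(mouse_id = "m1", position_id = "p1", track_id = "1",
#'                  t = c(0, 1/3), x = c(0, 2), y = 0)
#' TrackTable(df)
#' @export
TrackTable <- function(data, extraFeatures = character()) {
    stopifnot(is.data.frame(data))
    data$mouse_id <- as.character(data$mouse_id)
    data$position_id <- as.character(data$position_id)
    data$track_id <- as.character(data$track_id)
    dim3 <- "z" %in% names(data) && nrow(data) > 0 && any(data$z != 0)
    if (!"z" %in% names(data)) data$z <- rep(0, nrow(data))
    if (!"dist_to_edge" %in% names(data)) {
        data$dist_to_edge <- rep(NA_real_, nrow(data))
    }
    front <- c("mouse_id", "position_id", "track_id", "t", "x", "y", "z",
               "dist_to_edge")
    data <- data[, c(front, setdiff(names(data), front)), drop = FALSE]
    if (nrow(data)) {
        o <- order(data$mouse_id, data$position_id, data$track_id, data$t)
        data <- data[o, , drop = FALSE]
        rownames(data) <- NULL
    }
    new("TrackTable", data = data,
        dimensionality = if (dim3) 3L else 2L,
        extraFeatures = as.character(extraFeatures))
}

#' Uniform multivariate feature tensor
#'
#' Tracks x timepoints x features array produced by
#' [computeKineticFeatures()]: interpolation-complete (no missing values),
#' on a single uniform time grid, all tracks cropped to the same length.
#'
#' @slot values numeric array, tracks x timepoints x features.
#' @slot trackIndex character, global track ids (mouse.position.track).
#' @slot timeGrid numeric, uniform timepoints in hours.
#' @slot featureNames character, ordered feature names.
#' @slot provenance named character, "computed" or "passthrough" per
#'   feature.
#' @exportClass FeatureTensor
setClass("FeatureTensor",
    representation(
        values = "array", trackIndex = "character", timeGrid = "numeric",
        featureNames = "character", provenance = "character"
    )
)

setValidity("FeatureTensor", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array")
    if (d[1] != length(object@trackIndex)) return("trackIndex length mismatch")
    if (d[2] != length(object@timeGrid)) return("timeGrid length mismatch")
    if (d[3] != length(object@featureNames)) {
        return("featureNames length mismatch")
    }
    if (anyNA(object@values)) return("tensor contains missing values")
    g <- object@timeGrid
    if (length(g) >= 3 && diff(range(diff(g))) > 1e-9) {
        return("time grid spacing not constant")
    }
    TRUE
})

#' Per-timepoint principal-component series
#'
#' Output of [scaleAndPCA()]: every (track, timepoint) feature vector
#' standardized and projected onto the minimal number of principal
#' components whose cumulative explained variance reaches the configured
#' threshold.
#'
#' @slot values numeric array, tracks x timepoints x nPC.
#' @slot trackIndex,timeGrid as in [FeatureTensor-class].
#' @slot explainedVariance numeric, per-PC explained variance ratio for
#'   the full decomposition.
#' @slot nPC integer, number of retained components.
#' @slot varThreshold numeric, the cumulative-variance threshold used.
#' @exportClass PCSeries
setClass("PCSeries",
    representation(
        values = "array", trackIndex = "character", timeGrid = "numeric",
        explainedVariance = "numeric", nPC = "integer",
        varThreshold = "numeric"
    )
)

setValidity("PCSeries", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[3] != object@nPC) return("values/nPC mismatch")
    cv <- cumsum(object@explainedVariance)
    m <- object@nPC
    if (cv[m] < object@varThreshold - 1e-9) {
        return("retained PCs explain less than the threshold")
    }
    if (m > 1 && cv[m - 1] >= object@varThreshold - 1e-9) {
        return("nPC is not minimal for the threshold")
    }
    TRUE
})

#' Behavioral clustering result
#'
#' Output of [embedAndCluster()]: a 2D embedding of the DTW
#' cross-distance matrix plus a k-means (or PAM) cluster label per track.
#' Labels are integers 1..k (R convention); every cluster is non-empty.
#' The `summary` slot is filled by [characterizeClusters()].
#'
#' @slot trackIndex character, global track ids.
#' @slot embedding numeric n x 2 matrix of embedding coordinates.
#' @slot labels integer cluster label per track, values in 1..k.
#' @slot k integer number of clusters.
#' @slot summary data.frame of per-cluster feature means (filled by
#'   [characterizeClusters()], empty otherwise).
#' @slot seed integer random seed used.
#' @slot params list of all hyperparameters used.
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(
        trackIndex = "character", embedding = "matrix",
        labels = "integer", k = "integer", summary = "data.frame",
        seed = "integer", params = "list"
    ),
    prototype(summary = data.frame())
)

setValidity("ClusterResult", function(object) {
    n <- length(object@trackIndex)
    if (nrow(object@embedding) != n || ncol(object@embedding) != 2L) {
        return("embedding must be n x 2")
    }
    if (length(object@labels) != n) return("labels length mismatch")
    if (n == 0L) return(TRUE)
    if (!all(object@labels %in% seq_len(object@k))) {
        return("labels must lie in 1..k")
    }
    if (length(unique(object@labels)) != object@k) {
        return("every cluster must be non-empty")
    }
    TRUE
})

#' Static microenvironment component point cloud
#'
#' A named set of 3D coordinates for one tumor-microenvironment
#' component (e.g. SR101+ astrocytes/oligodendrocytes, CD20r+ macrophages,
#' CD31+ blood-vessel spots), treated as a static snapshot against which
#' per-timepoint cell positions are measured. `objectKind` records how the
#' objects were rendered upstream -- "spot" (centroid) or "surface_sample"
#' (boundary sample points) -- and selects the default proximity
#' threshold in [classifyProximity()].
#'
#' @slot componentName single string, e.g. "SR101", "CD20r", "BV".
#' @slot points numeric n x 3 matrix of coordinates (µm).
#' @slot objectKind "spot" or "surface_sample".
#' @slot positionId single string; NA means the cloud applies to all
#'   imaging positions.
#' @exportClass TMEComponentSet
setClass("TMEComponentSet",
    representation(
        componentName = "character", points = "matrix",
        objectKind = "character", positionId = "character"
    ),
    prototype(positionId = NA_character_)
)

setValidity("TMEComponentSet", function(object) {
    if (length(object@componentName) != 1L) return("one componentName")
    if (!object@objectKind %in% c("spot", "surface_sample")) {
        return("objectKind must be 'spot' or 'surface_sample'")
    }
    p <- object@points
    if (ncol(p) != 3L) return("points must be n x 3")
    if (nrow(p) && !all(is.finite(p))) return("non-finite coordinates")
    TRUE
})

#' Construct a TMEComponentSet
#'
#' @param componentName component label, e.g. "BV".
#' @param points numeric matrix (n x 2 or n x 3) of coordinates in µm;
#'   2D input is padded with z = 0.
#' @param objectKind "spot" or "surface_sample".
#' @param positionId imaging position the cloud belongs to, or NA for all.
#' @return a [TMEComponentSet-class] object.
#' @export
TMEComponentSet <- function(componentName, points,
                            objectKind = c("spot", "surface_sample"),
                            positionId = NA_character_) {
    objectKind <- match.arg(objectKind)
    points <- as.matrix(points)
    if (ncol(points) == 2L) points <- cbind(points, 0)
    storage.mode(points) <- "double"
    colnames(points) <- c("x", "y", "z")
    new("TMEComponentSet", componentName = componentName, points = points,
        objectKind = objectKind, positionId = as.character(positionId))
}
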