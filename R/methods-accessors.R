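#' @describeIn accessors per-timepoint data.frame of a TrackTable.
#' @export
setMethod("trackData", "TrackTable", function(object) object@data)

# global track id: one string per track, unique across mice/positions
.globalIds <- function(df) {
    paste(df$mouse_id, df$position_id, df$track_id, sep = ".")
}

#' @describeIn accessors unique global track ids (mouse.position.track).
#' @export
setMethod("trackIds", "TrackTable",
          function(object) unique(.globalIds(object@data)))

#' @describeIn accessors number of tracks.
#' @export
setMethod("nTracks", "TrackTable",
          function(object) length(trackIds(object)))

#' @describeIn accessors track ids of a FeatureTensor.
#' @export
setMethod("trackIds", "FeatureTensor", function(object) object@trackIndex)

#' @describeIn accessors number of tracks in a FeatureTensor.
#' @export
setMethod("nTracks", "FeatureTensor",
          function(object) length(object@trackIndex))

#' @describeIn accessors uniform time grid (hours).
#' @export
setMethod("timeGrid", "FeatureTensor", function(object) object@timeGrid)

#' @describeIn accessors feature names of the tensor.
#' @export
setMethod("featureNames", "FeatureTensor",
          function(object) object@featureNames)

#' @describeIn accessors the tracks x time x features array.
#' @export
setMethod("tensorValues", "FeatureTensor", function(object) object@values)

#' @describeIn accessors track ids of a PCSeries.
#' @export
setMethod("trackIds", "PCSeries", function(object) object@trackIndex)

#' @describeIn accessors PC series array (tracks x time x nPC).
#' @export
setMethod("tensorValues", "PCSeries", function(object) object@values)

#' @describeIn accessors time grid of a PCSeries.
#' @export
setMethod("timeGrid", "PCSeries", function(object) object@timeGrid)

#' @describeIn accessors per-PC explained variance ratios.
#' @export
setMethod("explainedVariance", "PCSeries",
          function(object) object@explainedVariance)

#' @describeIn accessors track ids of a ClusterResult.
#' @export
setMethod("trackIds", "ClusterResult", function(object) object@trackIndex)

#' @describeIn accessors integer cluster label (1..k) per track.
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) {
    setNames(object@labels, object@trackIndex)
})

#' @describeIn accessors n x 2 embedding coordinates.
#' @export
setMethod("clusterEmbedding", "ClusterResult",
          function(object) object@embedding)

#' @describeIn accessors per-cluster feature summary table.
#' @export
setMethod("clusterSummary", "ClusterResult", function(object) object@summary)

#' @describeIn accessors n x 3 coordinate matrix of a component cloud.
#' @export
setMethod("componentPoints", "TMEComponentSet",
          function(object) object@points)

setMethod("show", "TrackTable", function(object) {
    df <- object@data
    cat("TrackTable:", nTracks(object), "tracks,", nrow(df), "rows,",
        paste0(object@dimensionality, "D"), "\n")
    if (nrow(df)) {
        cat("  mice:", length(unique(df$mouse_id)),
            " positions:", length(unique(paste(df$mouse_id,
                                               df$position_id))), "\n")
        cat("  t range:", sprintf("%.3f..%.3f", min(df$t), max(df$t)),
            object@timeUnit, "\n")
        cat("  dist_to_edge:",
            if (all(is.na(df$dist_to_edge))) "absent" else "present", "\n")
    }
    if (length(object@extraFeatures)) {
        cat("  extra features:",
            paste(object@extraFeatures, collapse = ", "), "\n")
    }
})

setMethod("show", "FeatureTensor", function(object) {
    d <- dim(object@values)
    cat("FeatureTensor:", d[1], "tracks x", d[2], "timepoints x", d[3],
        "features\n")
    cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
    if (length(object@timeGrid) > 1) {
        cat("  dt:", sprintf("%.4f h", diff(object@timeGrid)[1]), "\n")
    }
})

setMethod("show", "PCSeries", function(object) {
    cat("PCSeries:", length(object@trackIndex), "tracks,",
        object@nPC, "PCs retained (cumulative variance",
        sprintf("%.1f%%", 100 * sum(
            object@explainedVariance[seq_len(object@nPC)])),
        ">= threshold", sprintf("%.0f%%)", 100 * object@varThreshold), "\n")
})

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", length(object@trackIndex), "tracks, k =",
        object@k, "\n")
    if (length(object@labels)) {
        tab <- table(object@labels)
        cat("  cluster sizes:", paste(as.integer(tab), collapse = ", "),
            "\n")
    }
    cat("  seed:", object@seed, "\n")
})

setMethod("show", "TMEComponentSet", function(object) {
    cat("TMEComponentSet '", object@componentName, "': ",
        nrow(object@points), " points (", object@objectKind, ")",
        if (!is.na(object@positionId)) {
            paste0(", position ", object@positionId)
        } else "", "\n", sep = "")
})
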