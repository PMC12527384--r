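# Feature engineering: uniform resampling, common-length cropping and
# per-timepoint kinetic features.

.splitTracks <- function(df) {
    gid <- .globalIds(df)
    split(df, factor(gid, levels = unique(gid)))
}

#' Resample every track to a uniform time grid
#'
#' Tracking misses frames; downstream time-series comparison needs one
#' fixed time step. Each track is linearly interpolated onto the grid
#' t0, t0 + dt, ... limited to its own observed span (no extrapolation
#' beyond a track's first or last observation). Coordinates,
#' `dist_to_edge` and all numeric extra features are interpolated with
#' the same rule. Tracks whose span is shorter than `dt` cannot place two
#' grid points and are dropped with a warning.
#'
#' @param table a [TrackTable-class].
#' @param dt grid spacing in hours (e.g. 1/3 for a 20-min interval).
#' @return a [TrackTable-class] on the uniform grid.
#' @examples
#' df <- data.frame(mouse_id = "m", position_id = "p", track_id = "1",
#'                  t = c(0, 1, 3), x = c(0, 1, 3), y = 0)
#' trackData(interpolateToGrid(TrackTable(df), dt = 1))$x  # 0 1 2 3
#' @export
interpolateToGrid <- function(table, dt) {
    stopifnot(is(table, "TrackTable"), dt > 0)
    df <- trackData(table)
    numCols <- c("x", "y", "z", "dist_to_edge", table@extraFeatures)
    pieces <- lapply(.splitTracks(df), function(tr) {
        span <- max(tr$t) - min(tr$t)
        if (span < dt) return(NULL)
        grid <- seq(min(tr$t), max(tr$t), by = dt)
        out <- tr[rep(1L, length(grid)), , drop = FALSE]
        out$t <- grid
        for (cl in numCols) {
            v <- tr[[cl]]
            out[[cl]] <- if (all(is.na(v))) {
                NA_real_
            } else {
                approx(tr$t, v, xout = grid, method = "linear",
                       rule = 1)$y
            }
        }
        out
    })
    nDropped <- sum(vapply(pieces, is.null, logical(1)))
    if (nDropped > 0) {
        warning(nDropped, " track(s) spanning less than dt dropped",
                call. = FALSE)
    }
    res <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    rownames(res) <- NULL
    out <- TrackTable(res, extraFeatures = table@extraFeatures)
    out@dimensionality <- table@dimensionality
    out
}

#' Crop all tracks to the minimal common length
#'
#' Dynamic time warping compares series more reliably when all series
#' have the same support, so every track is truncated to its first L
#' grid points, with L the shortest track length in the table (tracks
#' are aligned at their own start). The chosen L is reported via the
#' `croppedLength` attribute and a message.
#'
#' @param table a [TrackTable-class] already on a uniform grid.
#' @return a [TrackTable-class] in which every track has exactly L rows.
#' @export
cropCommonLength <- function(table) {
    stopifnot(is(table, "TrackTable"))
    pieces <- .splitTracks(trackData(table))
    L <- min(vapply(pieces, nrow, integer(1)))
    if (L < 3L) {
        stop("minimal common length ", L, " < 3; apply minimum track ",
             "length filtering before cropping", call. = FALSE)
    }
    res <- do.call(rbind, lapply(pieces, function(tr) tr[seq_len(L), ]))
    rownames(res) <- NULL
    out <- TrackTable(res, extraFeatures = table@extraFeatures)
    out@dimensionality <- table@dimensionality
    attr(out@data, "croppedLength") <- L
    message("cropped all tracks to L = ", L, " timepoints")
    out
}

.kineticsOneTrack <- function(tr, dt, wantInvasion) {
    p <- as.matrix(tr[, c("x", "y", "z")])
    n <- nrow(p)
    step <- c(0, sqrt(rowSums((p[-1, , drop = FALSE] -
                               p[-n, , drop = FALSE])^2)))
    speed <- step / dt
    speed[1] <- 0
    disp_d <- sqrt(rowSums((p - matrix(p[1, ], n, 3, byrow = TRUE))^2))
    disp2 <- disp_d^2
    disp_l <- cumsum(step)
    persistence <- ifelse(disp_l > 0, disp_d / disp_l, 0)
    out <- cbind(speed = speed, disp2 = disp2, disp_d = disp_d,
                 disp_l = disp_l, persistence = persistence)
    if (wantInvasion) {
        de <- tr$dist_to_edge
        invasion <- c(0, diff(de) / dt)
        out <- cbind(out, invasion = invasion)
    }
    out
}

#' Compute per-timepoint kinetic features
#'
#' For each track on the cropped uniform grid (positions p_0..p_i,
#' spacing dt):
#' \itemize{
#'   \item `speed_i = ||p_i - p_{i-1}|| / dt` (µm/h; `speed_0 = 0`)
#'   \item `disp_d_i = ||p_i - p_0||` -- net displacement from start (µm)
#'   \item `disp2_i = disp_d_i^2` -- squared displacement (µm²)
#'   \item `disp_l_i = sum_{j<=i} ||p_j - p_{j-1}||` -- path length (µm)
#'   \item `persistence_i = disp_d_i / disp_l_i` (0 when the path length
#'     is 0) -- movement efficiency in \[0, 1\]
#'   \item `invasion_i = (dist_to_edge_i - dist_to_edge_{i-1}) / dt` --
#'     velocity relative to the tumor edge (µm/h), positive when moving
#'     away from the edge; first timepoint 0
#' }
#'
#' @param table a cropped, uniform-grid [TrackTable-class].
#' @param features subset of the kinetic feature names above to compute;
#'   requesting "invasion" without a `dist_to_edge` column is an error.
#' @param passthrough extra feature columns (already interpolated) to
#'   append to the tensor unchanged.
#' @return a [FeatureTensor-class] (tracks x timepoints x features).
#' @export
computeKineticFeatures <- function(table,
                                   features = c("speed", "disp2", "disp_d",
                                                "disp_l", "persistence",
                                                "invasion"),
                                   passthrough = character()) {
    stopifnot(is(table, "TrackTable"))
    known <- c("speed", "disp2", "disp_d", "disp_l", "persistence",
               "invasion")
    bad <- setdiff(features, known)
    if (length(bad)) {
        stop("unknown kinetic features: ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
    df <- trackData(table)
    hasEdge <- !all(is.na(df$dist_to_edge))
    if ("invasion" %in% features && !hasEdge) {
        stop("feature 'invasion' requires a 'dist_to_edge' column; none ",
             "is present", call. = FALSE)
    }
    bad <- setdiff(passthrough, table@extraFeatures)
    if (length(bad)) {
        stop("passthrough features absent from table: ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    pieces <- .splitTracks(df)
    lens <- vapply(pieces, nrow, integer(1))
    if (length(unique(lens)) != 1L) {
        stop("tracks differ in length; run cropCommonLength() first",
             call. = FALSE)
    }
    L <- lens[1]
    grid <- pieces[[1]]$t - pieces[[1]]$t[1]
    dt <- if (L > 1) grid[2] - grid[1] else NA_real_
    featNames <- c(intersect(known, features), passthrough)
    arr <- array(NA_real_,
                 dim = c(length(pieces), L, length(featNames)),
                 dimnames = list(names(pieces), NULL, featNames))
    for (i in seq_along(pieces)) {
        kin <- .kineticsOneTrack(pieces[[i]], dt,
                                 "invasion" %in% features)
        for (f in intersect(known, features)) arr[i, , f] <- kin[, f]
        for (f in passthrough) arr[i, , f] <- pieces[[i]][[f]]
    }
    prov <- setNames(c(rep("computed", length(intersect(known, features))),
                       rep("passthrough", length(passthrough))), featNames)
    new("FeatureTensor", values = arr, trackIndex = names(pieces),
        timeGrid = grid, featureNames = featNames, provenance = prov)
}

#' Dump a feature tensor in long format for audit
#'
#' One row per (track, timepoint, feature) with the value, written as
#' plain CSV.
#'
#' @param tensor a [FeatureTensor-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTensorLong <- function(tensor, path) {
    stopifnot(is(tensor, "FeatureTensor"))
    d <- dim(tensor@values)
    out <- data.frame(
        track_id = rep(tensor@trackIndex, times = d[2] * d[3]),
        t = rep(rep(tensor@timeGrid, each = d[1]), times = d[3]),
        feature = rep(tensor@featureNames, each = d[1] * d[2]),
        value = as.numeric(tensor@values),
        stringsAsFactors = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Summarize each feature per track
#'
#' Collapses the time axis: per track and feature, the time mean
#' (`mean_<f>`) and the range max - min (`<f>_range`, the variability of
#' that feature over the track's observation window).
#'
#' @param tensor a [FeatureTensor-class].
#' @return data.frame with one row per track: `track_id`, then
#'   `mean_<f>` and `<f>_range` columns.
#' @export
summarizeTrackFeatures <- function(tensor) {
    stopifnot(is(tensor, "FeatureTensor"))
    v <- tensor@values
    out <- data.frame(track_id = tensor@trackIndex,
                      stringsAsFactors = FALSE)
    for (j in seq_along(tensor@featureNames)) {
        f <- tensor@featureNames[j]
        m <- v[, , j, drop = FALSE]
        dim(m) <- dim(v)[1:2]
        out[[paste0("mean_", f)]] <- rowMeans(m)
        out[[paste0(f, "_range")]] <- apply(m, 1, max) - apply(m, 1, min)
    }
    out
}
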