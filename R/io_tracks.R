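# Readers for the supported tracking-export dialects. Every reader
# converts units once at the boundary (frames -> hours, coordinates are
# taken to be micrometers) and returns the canonical TrackTable.

.checkDecimal <- function(x, file, col) {
    bad <- grepl(",", x, fixed = TRUE)
    if (any(bad)) {
        stop("comma decimal separator in ", file, " column '", col,
             "' (rows ", paste(head(which(bad), 5), collapse = ", "),
             "); export with '.' decimals", call. = FALSE)
    }
}

.asNum <- function(x, file, col) {
    .checkDecimal(x, file, col)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "")
    if (length(bad)) {
        stop("non-numeric value in ", file, " column '", col, "' at row ",
             bad[1], ": '", x[bad[1]], "'", call. = FALSE)
    }
    v
}

# drop tracks shorter than minLen, keeping a tally for the caller
.dropShortTracks <- function(df, minLen = 2L) {
    key <- paste(df$mouse_id, df$position_id, df$track_id, sep = "\r")
    n <- table(key)
    short <- names(n)[n < minLen]
    list(data = df[!key %in% short, , drop = FALSE],
         dropped = length(short))
}

#' Read a set of Imaris per-statistic CSV exports
#'
#' Imaris exports track statistics as one CSV per statistic, sharing
#' (TrackID, Time) keys with the Position export. Each file carries the
#' statistic name on its first line and the column header on the second.
#' All statistic files are inner-joined onto the Position rows; keys
#' present on one side only abort with a list of orphans, so silent row
#' loss cannot occur.
#'
#' @param paths character vector of file paths; exactly one must be the
#'   Position export (identified by its "Position X" column).
#' @param edge_column name of the statistic to interpret as the distance
#'   to the tumor-edge surface (mapped to `dist_to_edge`), or NULL. Which
#'   Imaris statistic carries that distance depends on how the edge
#'   surface was set up, so it is a user choice rather than a guess.
#' @param frame_interval time between frames in hours (Imaris `Time` is a
#'   1-based frame index). Default 1/3 h (20 min).
#' @param mouse_id,position_id labels attached to every row.
#' @return [TrackTable-class]; statistic values are kept verbatim as
#'   extra features named after their statistic.
#' @export
readImarisExport <- function(paths, edge_column = NULL,
                             frame_interval = 1 / 3,
                             mouse_id = "m1", position_id = "p1") {
    stopifnot(length(paths) >= 1, frame_interval > 0)
    parsed <- lapply(paths, .readImarisFile)
    isPos <- vapply(parsed, function(p) p$kind == "position", logical(1))
    if (sum(isPos) != 1L) {
        stop("expected exactly one Position file among the exports",
             call. = FALSE)
    }
    pos <- parsed[[which(isPos)]]
    if (nrow(pos$data) == 0L) {
        stop("Position file ", paths[which(isPos)], " has no data rows",
             call. = FALSE)
    }
    df <- pos$data
    key <- paste(df$TrackID, df$Time, sep = "\r")
    if (anyDuplicated(key)) {
        stop("duplicate (TrackID, Time) keys in Position file: ",
             paste(head(unique(key[duplicated(key)]), 5), collapse = "; "),
             call. = FALSE)
    }
    extras <- character()
    for (p in parsed[!isPos]) {
        skey <- paste(p$data$TrackID, p$data$Time, sep = "\r")
        if (anyDuplicated(skey)) {
            stop("duplicate (TrackID, Time) keys in statistic '", p$name,
                 "'", call. = FALSE)
        }
        orphan <- c(setdiff(key, skey), setdiff(skey, key))
        if (length(orphan)) {
            stop("statistic '", p$name, "' keys do not match Position ",
                 "export; orphans: ",
                 paste(head(gsub("\r", "@t", orphan), 5), collapse = "; "),
                 call. = FALSE)
        }
        df[[p$name]] <- p$data$Value[match(key, skey)]
        extras <- c(extras, p$name)
    }
    out <- data.frame(
        mouse_id = mouse_id, position_id = position_id,
        track_id = as.character(df$TrackID),
        t = (df$Time - 1) * frame_interval,
        x = df$x, y = df$y, z = df$z,
        stringsAsFactors = FALSE
    )
    for (e in extras) out[[e]] <- df[[e]]
    if (!is.null(edge_column)) {
        if (!edge_column %in% extras) {
            stop("edge_column '", edge_column,
                 "' not among exported statistics (",
                 paste(extras, collapse = ", "), ")", call. = FALSE)
        }
        out$dist_to_edge <- out[[edge_column]]
        out[[edge_column]] <- NULL
        extras <- setdiff(extras, edge_column)
    }
    ds <- .dropShortTracks(out)
    tab <- TrackTable(ds$data, extraFeatures = extras)
    attr(tab@data, "droppedShortTracks") <- ds$dropped
    tab
}

.readImarisFile <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 2L) {
        stop("Imaris export ", path, " is empty", call. = FALSE)
    }
    name <- trimws(strsplit(lines[1], ",")[[1]][1])
    body <- read.csv(text = paste(lines[-1], collapse = "\n"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("Position X", "Position Y") %in% names(body))) {
        d <- data.frame(
            x = .asNum(as.character(body[["Position X"]]), path, "Position X"),
            y = .asNum(as.character(body[["Position Y"]]), path, "Position Y"),
            z = if ("Position Z" %in% names(body)) {
                .asNum(as.character(body[["Position Z"]]), path, "Position Z")
            } else 0,
            Time = .asNum(as.character(body[["Time"]]), path, "Time"),
            TrackID = as.character(body[["TrackID"]]),
            stringsAsFactors = FALSE
        )
        list(kind = "position", name = name, data = d)
    } else if ("Value" %in% names(body)) {
        d <- data.frame(
            Value = .asNum(as.character(body[["Value"]]), path, "Value"),
            Time = .asNum(as.character(body[["Time"]]), path, "Time"),
            TrackID = as.character(body[["TrackID"]]),
            stringsAsFactors = FALSE
        )
        list(kind = "statistic", name = name, data = d)
    } else {
        stop("unrecognized Imaris export layout in ", path, call. = FALSE)
    }
}

#' Read a TrackMate "allspots" CSV
#'
#' TrackMate writes the machine-readable column ids on the first line and
#' up to three further non-numeric header lines (human-readable names and
#' units) that vary across versions; these are detected by sniffing
#' non-numeric `POSITION_X` cells and skipped. Spots whose `TRACK_ID` is
#' missing or "None" (unassigned spots) are dropped and counted in the
#' `droppedSpots` attribute of the returned table's data.
#'
#' @param path path to the allspots CSV.
#' @param frame_interval hours per frame; `FRAME` is 0-based, so
#'   `t = FRAME * frame_interval`.
#' @param track_column name of the track id column (default "TRACK_ID").
#' @param mouse_id,position_id labels attached to every row.
#' @return [TrackTable-class] with morphology columns (AREA, SOLIDITY,
#'   SHAPE_INDEX, ellipse axes, ...) retained as extra features.
#' @export
readTrackMateSpots <- function(path, frame_interval = 1 / 3,
                               track_column = "TRACK_ID",
                               mouse_id = "m1", position_id = "p1") {
    stopifnot(frame_interval > 0)
    raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
    if (!track_column %in% names(raw)) {
        stop("column '", track_column, "' absent from ", path, call. = FALSE)
    }
    need <- c("POSITION_X", "POSITION_Y")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
        stop("missing columns in ", path, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!any(c("FRAME", "POSITION_T") %in% names(raw))) {
        stop("need a FRAME or POSITION_T column in ", path, call. = FALSE)
    }
    # skip extra header rows (human names / units): non-numeric POSITION_X
    hdr <- suppressWarnings(is.na(as.numeric(raw$POSITION_X)))
    hdr[grepl(",", raw$POSITION_X, fixed = TRUE)] <- FALSE # commas -> error later
    raw <- raw[!(hdr & seq_len(nrow(raw)) <= 3L), , drop = FALSE]
    tid <- trimws(raw[[track_column]])
    unassigned <- is.na(tid) | tid == "" | tolower(tid) == "none" |
        tolower(tid) == "na"
    dropped <- sum(unassigned)
    raw <- raw[!unassigned, , drop = FALSE]
    frameCol <- if ("FRAME" %in% names(raw)) "FRAME" else "POSITION_T"
    out <- data.frame(
        mouse_id = rep(mouse_id, nrow(raw)),
        position_id = rep(position_id, nrow(raw)),
        track_id = trimws(raw[[track_column]]),
        t = .asNum(raw[[frameCol]], path, frameCol) *
            (if (frameCol == "FRAME") frame_interval else 1),
        x = .asNum(raw$POSITION_X, path, "POSITION_X"),
        y = .asNum(raw$POSITION_Y, path, "POSITION_Y"),
        z = if ("POSITION_Z" %in% names(raw)) {
            .asNum(raw$POSITION_Z, path, "POSITION_Z")
        } else 0,
        stringsAsFactors = FALSE
    )
    reserved <- c("LABEL", "ID", track_column, "QUALITY", "POSITION_X",
                  "POSITION_Y", "POSITION_Z", "POSITION_T", "FRAME",
                  "VISIBILITY", "MANUAL_SPOT_COLOR")
    extras <- character()
    for (cl in setdiff(names(raw), reserved)) {
        v <- suppressWarnings(as.numeric(raw[[cl]]))
        if (nrow(raw) == 0L || !all(is.na(v))) {
            out[[cl]] <- v
            extras <- c(extras, cl)
        }
    }
    ds <- .dropShortTracks(out)
    tab <- TrackTable(ds$data, extraFeatures = extras)
    attr(tab@data, "droppedSpots") <- dropped
    attr(tab@data, "droppedShortTracks") <- ds$dropped
    tab
}

#' Read an MTrackJ or ManualTracking point export
#'
#' Both Fiji dialects are point lists: a track index, a point index or
#' slice number, and x/y (z optional for MTrackJ). Slice numbers are
#' 1-based frames and are converted to hours. Tracks with a single point
#' cannot yield kinetics and are dropped; their count is stored in the
#' `droppedShortTracks` attribute with a warning.
#'
#' @param path file path.
#' @param dialect "mtrackj" (columns TID, PID, x, y \[, z\], Slice) or
#'   "manual_tracking" (columns Track, Slice, X, Y).
#' @param frame_interval hours per frame.
#' @param mouse_id,position_id labels attached to every row.
#' @return [TrackTable-class]; 2D input is stored with z = 0.
#' @export
readFijiManual <- function(path, dialect = c("mtrackj", "manual_tracking"),
                           frame_interval = 1 / 3,
                           mouse_id = "m1", position_id = "p1") {
    dialect <- match.arg(dialect)
    stopifnot(frame_interval > 0)
    raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
    if (dialect == "mtrackj") {
        need <- c("TID", "PID", "x", "y", "Slice")
        miss <- setdiff(need, names(raw))
        if (length(miss)) {
            stop("mtrackj export missing columns: ",
                 paste(miss, collapse = ", "), call. = FALSE)
        }
        out <- data.frame(
            mouse_id = mouse_id, position_id = position_id,
            track_id = raw$TID,
            t = (.asNum(raw$Slice, path, "Slice") - 1) * frame_interval,
            x = .asNum(raw$x, path, "x"),
            y = .asNum(raw$y, path, "y"),
            z = if ("z" %in% names(raw)) .asNum(raw$z, path, "z") else 0,
            stringsAsFactors = FALSE
        )
    } else {
        need <- c("Track", "Slice", "X", "Y")
        miss <- setdiff(need, names(raw))
        if (length(miss)) {
            stop("manual_tracking export missing columns: ",
                 paste(miss, collapse = ", "), call. = FALSE)
        }
        out <- data.frame(
            mouse_id = mouse_id, position_id = position_id,
            track_id = raw$Track,
            t = (.asNum(raw$Slice, path, "Slice") - 1) * frame_interval,
            x = .asNum(raw$X, path, "X"),
            y = .asNum(raw$Y, path, "Y"),
            z = 0,
            stringsAsFactors = FALSE
        )
    }
    ds <- .dropShortTracks(out)
    if (ds$dropped > 0) {
        warning(ds$dropped, " track(s) of length 1 dropped", call. = FALSE)
    }
    tab <- TrackTable(ds$data)
    attr(tab@data, "droppedShortTracks") <- ds$dropped
    tab
}

#' Write a back-projection table
#'
#' Re-attaches cluster labels to the original per-timepoint records so
#' the clustering can be visualized in the source imaging software
#' (importable as a spot annotation table). Column order is fixed:
#' mouse_id, position_id, track_id, t, x, y, z, cluster, cluster_color.
#'
#' @param result [ClusterResult-class] with labels per track.
#' @param table the [TrackTable-class] the clustering was derived from.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeBackprojection <- function(result, table, path) {
    stopifnot(is(result, "ClusterResult"), is(table, "TrackTable"))
    df <- trackData(table)
    gid <- .globalIds(df)
    missing <- setdiff(trackIds(result), unique(gid))
    if (length(missing)) {
        stop("labeled tracks absent from the track table: ",
             paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    lab <- clusterLabels(result)
    keep <- gid %in% names(lab)
    out <- df[keep, c("mouse_id", "position_id", "track_id", "t",
                      "x", "y", "z"), drop = FALSE]
    out$cluster <- as.integer(lab[gid[keep]])
    out$cluster_color <- out$cluster
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write / read the canonical track table CSV
#'
#' Plain UTF-8 comma-separated dump of a [TrackTable-class], used for all
#' pipeline intermediates. `readTrackTable()` restores extra feature
#' columns by name.
#'
#' @param table a [TrackTable-class].
#' @param path CSV path.
#' @return `writeTrackTable()` the path invisibly; `readTrackTable()` a
#'   [TrackTable-class].
#' @export
writeTrackTable <- function(table, path) {
    stopifnot(is(table, "TrackTable"))
    write.csv(trackData(table), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    base <- c("mouse_id", "position_id", "track_id", "t", "x", "y", "z",
              "dist_to_edge")
    TrackTable(df, extraFeatures = setdiff(names(df), base))
}
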