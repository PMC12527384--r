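# Synthetic-data generator: persistent biased random walks with planted
# behavioral archetypes, a planar tumor-edge reference, static TME point
# clouds, a per-position region partition, and fixture writers for every
# supported tracking-export dialect.
#
# The motion model is a stand-in with analytically checkable limiting
# cases, not a claim about tumor-cell biology: per frame the direction
# is normalize(p * prev_dir + (1 - p) * u + b * e_x) with u uniform on
# the unit sphere, the step length is Gamma-distributed with the
# archetype's mean, and the tumor occupies x < 0 so dist_to_edge =
# max(x, 0).

#' Archetype parameter presets
#'
#' Seven behavioral archetypes named by the motility vocabulary of the
#' field: invading / slow invading (directed away from the tumor edge),
#' retreating / slow retreating (directed back toward it), erratic
#' (fast, non-directed), slow (non-directed), static. The "easy" regime
#' is strongly separated; "hard" shrinks the contrasts and adds noise.
#'
#' @param regime "easy" or "hard".
#' @param n_tracks tracks per archetype.
#' @return data.frame with columns `name`, `mean_step` (µm per frame),
#'   `persistence` (directional persistence p in \[0, 1\]),
#'   `edge_drift` (b in \[-1, 1\], positive = away from the edge),
#'   `noise_sd` (µm), `n_tracks`.
#' @export
archetypePresets <- function(regime = c("easy", "hard"), n_tracks = 40L) {
    regime <- match.arg(regime)
    base <- data.frame(
        name = c("invading", "slow invading", "retreating",
                 "slow retreating", "erratic", "slow", "static"),
        stringsAsFactors = FALSE
    )
    if (regime == "easy") {
        base$mean_step <- c(4.0, 1.5, 4.0, 1.5, 4.0, 1.5, 0.15)
        base$persistence <- c(0.9, 0.8, 0.9, 0.8, 0.05, 0.2, 0.0)
        base$edge_drift <- c(0.8, 0.6, -0.8, -0.6, 0.0, 0.0, 0.0)
        base$noise_sd <- c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.1)
    } else {
        base$mean_step <- c(3.0, 1.8, 3.0, 1.8, 3.0, 1.8, 0.5)
        base$persistence <- c(0.7, 0.6, 0.7, 0.6, 0.1, 0.2, 0.0)
        base$edge_drift <- c(0.4, 0.3, -0.4, -0.3, 0.0, 0.0, 0.0)
        base$noise_sd <- c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.4)
    }
    base$n_tracks <- as.integer(n_tracks)
    base
}

#' Scene configuration for the simulator
#'
#' Collects every knob of the synthetic study design. Defaults mirror
#' the acquisition the package targets: 20-min frame interval
#' (dt = 1/3 h), a planar tumor edge at x = 0 with tumor at x < 0, and a
#' static vessel snapshot.
#'
#' @param archetypes data.frame as from [archetypePresets()].
#' @param n_timepoints frames per track (>= 3).
#' @param dt frame interval in hours.
#' @param n_mice,positions_per_mouse study layout.
#' @param dropout_rate per-frame missing probability in \[0, 0.5\].
#' @param x_range,box_size start x range (µm from the edge) and lateral
#'   extent of each position (µm).
#' @param step_shape Gamma shape of the step-length distribution.
#' @param region_labels region names assigned round-robin to positions.
#' @param region_enrichment named list: region -> named numeric of
#'   archetype multipliers for the track counts in that region's
#'   positions (plants region-specific behavior enrichment).
#' @param components named list: component -> `list(n = , kind = )`
#'   Poisson point-cloud specs (kind "spot" or "surface_sample").
#' @param vessels `list(n = , spacing = , length = , along_archetype = )`;
#'   when `along_archetype` names an archetype, each vessel polyline is
#'   laid through a start site of that archetype along the +x drift
#'   axis, planting vascular proximity for it.
#' @param enrich `list(component = , archetype = , radius = , factor = )`
#'   or NULL: boosts a point component's intensity within `radius` µm of
#'   the named archetype's track points.
#' @param seed integer seed; recorded in every output.
#' @return a list with class "SceneConfig".
#' @export
sceneConfig <- function(archetypes = archetypePresets("easy"),
                        n_timepoints = 9L, dt = 1 / 3,
                        n_mice = 1L, positions_per_mouse = 1L,
                        dropout_rate = 0.1,
                        x_range = c(10, 60), box_size = 150,
                        step_shape = 4,
                        region_labels = NULL,
                        region_enrichment = NULL,
                        components = list(),
                        vessels = NULL,
                        enrich = NULL,
                        seed = 42L) {
    if (n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
    if (dropout_rate < 0 || dropout_rate > 0.5) {
        stop("dropout_rate must lie in [0, 0.5]", call. = FALSE)
    }
    stopifnot(dt > 0, n_mice >= 1, positions_per_mouse >= 1)
    structure(list(
        archetypes = archetypes, n_timepoints = as.integer(n_timepoints),
        dt = dt, n_mice = as.integer(n_mice),
        positions_per_mouse = as.integer(positions_per_mouse),
        dropout_rate = dropout_rate, x_range = x_range,
        box_size = box_size, step_shape = step_shape,
        region_labels = region_labels,
        region_enrichment = region_enrichment,
        components = components, vessels = vessels, enrich = enrich,
        seed = as.integer(seed)
    ), class = "SceneConfig")
}

.unitSphere <- function() {
    repeat {
        v <- rnorm(3)
        n <- sqrt(sum(v^2))
        if (n > 1e-12) return(v / n)
    }
}

.simulateOneTrack <- function(arch, cfg) {
    nT <- cfg$n_timepoints
    p <- arch$persistence; b <- arch$edge_drift
    pos <- matrix(NA_real_, nT, 3)
    pos[1, ] <- c(runif(1, cfg$x_range[1], cfg$x_range[2]),
                  runif(1, 0, cfg$box_size), runif(1, 0, cfg$box_size))
    prev <- if (b != 0) c(sign(b), 0, 0) else .unitSphere()
    for (i in 2:nT) {
        w <- p * prev + (1 - p) * .unitSphere() + b * c(1, 0, 0)
        nw <- sqrt(sum(w^2))
        dir <- if (nw > 1e-12) w / nw else .unitSphere()
        len <- if (arch$mean_step > 0) {
            rgamma(1, shape = cfg$step_shape,
                   rate = cfg$step_shape / arch$mean_step)
        } else 0
        noise <- if (arch$noise_sd > 0) rnorm(3, sd = arch$noise_sd) else 0
        pos[i, ] <- pos[i - 1, ] + dir * len + noise
        prev <- dir
    }
    pos
}

.positionLayout <- function(cfg) {
    mice <- sprintf("m%d", seq_len(cfg$n_mice))
    layout <- expand.grid(position = seq_len(cfg$positions_per_mouse),
                          mouse_id = mice, stringsAsFactors = FALSE)
    layout$position_id <- sprintf("p%d", layout$position)
    nPos <- nrow(layout)
    layout$region_label <- if (is.null(cfg$region_labels)) {
        NA_character_
    } else {
        rep_len(cfg$region_labels, nPos)
    }
    layout[, c("mouse_id", "position_id", "region_label")]
}

#' Simulate tracks with planted behavioral archetypes
#'
#' Generates a persistent biased random walk per track (see the
#' archetype parameters), applies frame dropout, and returns the track
#' table together with the planted ground truth. The tumor edge is the
#' plane x = 0 (tumor at x < 0), so `dist_to_edge = max(x, 0)` and the
#' drift parameter maps directly onto the invasion-velocity feature.
#'
#' @param config a [sceneConfig()].
#' @return list: `table` (a [TrackTable-class]), `truth` (data.frame
#'   mouse_id, position_id, track_id, archetype), `regions` (data.frame
#'   mouse_id, position_id, region_label), `seed`.
#' @export
simulateTracks <- function(config) {
    stopifnot(inherits(config, "SceneConfig"))
    set.seed(config$seed)
    layout <- .positionLayout(config)
    rows <- list(); truth <- list()
    for (li in seq_len(nrow(layout))) {
        mouse <- layout$mouse_id[li]; posId <- layout$position_id[li]
        region <- layout$region_label[li]
        counter <- 0L
        for (ai in seq_len(nrow(config$archetypes))) {
            arch <- config$archetypes[ai, ]
            n <- arch$n_tracks
            if (!is.null(config$region_enrichment) && !is.na(region)) {
                mult <- config$region_enrichment[[region]]
                if (!is.null(mult) && arch$name %in% names(mult)) {
                    n <- max(1L, as.integer(round(n * mult[[arch$name]])))
                }
            }
            for (tr in seq_len(n)) {
                counter <- counter + 1L
                tid <- as.character(counter)
                pos <- .simulateOneTrack(arch, config)
                keep <- rbinom(config$n_timepoints, 1,
                               1 - config$dropout_rate) == 1
                if (sum(keep) < 2L) {
                    keep[sample.int(config$n_timepoints, 2)] <- TRUE
                }
                idx <- which(keep)
                rows[[length(rows) + 1L]] <- data.frame(
                    mouse_id = mouse, position_id = posId, track_id = tid,
                    t = (idx - 1L) * config$dt,
                    x = pos[idx, 1], y = pos[idx, 2], z = pos[idx, 3],
                    dist_to_edge = pmax(pos[idx, 1], 0),
                    stringsAsFactors = FALSE)
                truth[[length(truth) + 1L]] <- data.frame(
                    mouse_id = mouse, position_id = posId, track_id = tid,
                    archetype = arch$name, stringsAsFactors = FALSE)
            }
        }
    }
    tab <- TrackTable(do.call(rbind, rows))
    list(table = tab,
         truth = do.call(rbind, truth),
         regions = layout, seed = config$seed)
}

#' Simulate static TME component point clouds
#'
#' Vessels are polylines sampled at fixed spacing into "spot" points;
#' when `vessels$along_archetype` is set, each polyline passes through
#' the start site of a track of that archetype and runs along the +x
#' drift axis (planting vascular proximity for that archetype). Other
#' components are uniform Poisson point clouds per position, optionally
#' intensity-boosted within `enrich$radius` of the named archetype's
#' track points.
#'
#' @param config a [sceneConfig()].
#' @param sim output of [simulateTracks()] on the same config (needed
#'   for archetype-anchored placement).
#' @return list of [TMEComponentSet-class].
#' @export
simulateTME <- function(config, sim) {
    stopifnot(inherits(config, "SceneConfig"))
    set.seed(config$seed + 1L)
    df <- trackData(sim$table)
    comps <- list()
    layout <- unique(df[, c("mouse_id", "position_id")])
    for (li in seq_len(nrow(layout))) {
        mouse <- layout$mouse_id[li]; posId <- layout$position_id[li]
        sub <- df[df$mouse_id == mouse & df$position_id == posId, ]
        tr <- sim$truth[sim$truth$mouse_id == mouse &
                        sim$truth$position_id == posId, ]
        # vessels
        vs <- config$vessels
        if (!is.null(vs)) {
            n <- vs$n %||% 5L
            spacing <- vs$spacing %||% 3
            len <- vs$length %||% 60
            pts <- NULL
            for (v in seq_len(n)) {
                if (!is.null(vs$along_archetype)) {
                    cand <- tr$track_id[tr$archetype == vs$along_archetype]
                    if (!length(cand)) next
                    tid <- cand[1 + (v - 1) %% length(cand)]
                    st <- sub[sub$track_id == tid, ][1, ]
                    xs <- seq(st$x - len / 4, st$x + len, by = spacing)
                    pts <- rbind(pts, cbind(xs, st$y, st$z))
                } else {
                    y0 <- runif(1, 0, config$box_size)
                    z0 <- runif(1, 0, config$box_size)
                    x0 <- runif(1, config$x_range[1], config$x_range[2])
                    xs <- seq(x0, x0 + len, by = spacing)
                    pts <- rbind(pts, cbind(xs, y0, z0))
                }
            }
            if (!is.null(pts)) {
                comps[[length(comps) + 1L]] <- TMEComponentSet(
                    "BV", pts, objectKind = "spot", positionId = posId)
            }
        }
        # Poisson point clouds
        for (nm in names(config$components)) {
            spec <- config$components[[nm]]
            if (is.null(spec) || (spec$n %||% 0) <= 0) {
                warning("component '", nm, "' has zero intensity; empty",
                        call. = FALSE)
                comps[[length(comps) + 1L]] <- TMEComponentSet(
                    nm, matrix(numeric(0), 0, 3),
                    objectKind = spec$kind %||% "spot",
                    positionId = posId)
                next
            }
            nPts <- rpois(1, spec$n)
            pts <- cbind(runif(nPts, min(sub$x) - 10, max(sub$x) + 10),
                         runif(nPts, 0, config$box_size),
                         runif(nPts, 0, config$box_size))
            en <- config$enrich
            if (!is.null(en) && identical(en$component, nm) &&
                (en$radius %||% 0) > 0) {
                anchors <- sub[sub$track_id %in%
                               tr$track_id[tr$archetype == en$archetype], ]
                nExtra <- rpois(1, spec$n * ((en$factor %||% 2) - 1))
                if (nrow(anchors) && nExtra > 0) {
                    at <- anchors[sample.int(nrow(anchors), nExtra,
                                             replace = TRUE), ]
                    jit <- matrix(runif(nExtra * 3, -en$radius, en$radius),
                                  nExtra, 3)
                    pts <- rbind(pts, cbind(at$x, at$y, at$z) + jit)
                }
            }
            comps[[length(comps) + 1L]] <- TMEComponentSet(
                nm, pts, objectKind = spec$kind %||% "spot",
                positionId = posId)
        }
    }
    comps
}

#' Write / read TME component CSV
#'
#' Plain CSV with columns component_name, x, y, z, object_kind,
#' position_id.
#'
#' @param components list of [TMEComponentSet-class].
#' @param path CSV path.
#' @return `writeComponents()` the path invisibly; `readComponents()` a
#'   list of [TMEComponentSet-class].
#' @export
writeComponents <- function(components, path) {
    rows <- lapply(components, function(cp) {
        p <- componentPoints(cp)
        if (nrow(p) == 0L) return(NULL)
        data.frame(component_name = cp@componentName,
                   x = p[, 1], y = p[, 2], z = p[, 3],
                   object_kind = cp@objectKind,
                   position_id = cp@positionId,
                   stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeComponents
#' @export
readComponents <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    key <- paste(df$component_name, df$position_id, sep = "\r")
    lapply(split(df, factor(key, levels = unique(key))), function(d) {
        TMEComponentSet(d$component_name[1],
                        as.matrix(d[, c("x", "y", "z")]),
                        objectKind = d$object_kind[1],
                        positionId = d$position_id[1])
    })
}

#' Write tracking-export fixtures in a supported dialect
#'
#' Emits files laid out like the corresponding tracking software's
#' export (synthetic stand-ins for real exports, matching the published
#' column conventions), such that the matching reader parses them back
#' to the same table. One (mouse, position) per call.
#'
#' @param table single-position [TrackTable-class].
#' @param dialect "imaris", "trackmate", "mtrackj" or "manual_tracking"
#'   ("manual_tracking" is 2D-only and refuses tables with nonzero z).
#' @param dir output directory (created if needed).
#' @param frame_interval hours per frame; inferred from the time grid
#'   when NULL.
#' @return character vector of file paths written.
#' @export
writeFixtures <- function(table, dialect = c("imaris", "trackmate",
                                             "mtrackj", "manual_tracking"),
                          dir, frame_interval = NULL) {
    dialect <- match.arg(dialect)
    stopifnot(is(table, "TrackTable"))
    df <- trackData(table)
    if (nrow(unique(df[, c("mouse_id", "position_id")])) != 1L) {
        stop("fixtures are written one (mouse, position) at a time",
             call. = FALSE)
    }
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (is.null(frame_interval)) {
        dts <- diff(sort(unique(df$t)))
        frame_interval <- min(dts[dts > 1e-12])
    }
    frame <- as.integer(round(df$t / frame_interval))   # 0-based
    switch(dialect,
        imaris = {
            paths <- file.path(dir, "Position.csv")
            writeLines(c("Position",
                paste("Position X,Position Y,Position Z,Unit,Category,",
                      "Time,TrackID,ID", sep = ""),
                sprintf("%.17g,%.17g,%.17g,um,Spot,%d,%s,%d",
                        df$x, df$y, df$z, frame + 1L, df$track_id,
                        seq_len(nrow(df)))), paths)
            stats <- table@extraFeatures
            if (!all(is.na(df$dist_to_edge))) {
                stats <- c(stats, "EdgeDistance")
                df$EdgeDistance <- df$dist_to_edge
            }
            for (s in stats) {
                p <- file.path(dir, paste0(gsub("\\W", "_", s), ".csv"))
                writeLines(c(s, "Value,Unit,Category,Time,TrackID,ID",
                    sprintf("%.17g,um,Spot,%d,%s,%d", df[[s]], frame + 1L,
                            df$track_id, seq_len(nrow(df)))), p)
                paths <- c(paths, p)
            }
            paths
        },
        trackmate = {
            p <- file.path(dir, "allspots.csv")
            extras <- table@extraFeatures
            hdr <- c("LABEL", "ID", "TRACK_ID", "QUALITY", "POSITION_X",
                     "POSITION_Y", "POSITION_Z", "POSITION_T", "FRAME",
                     extras)
            human <- c("Label", "Spot ID", "Track ID", "Quality", "X",
                       "Y", "Z", "T", "Frame", extras)
            units <- c("", "", "", "(quality)", "(micron)", "(micron)",
                       "(micron)", "(sec)", "", rep("", length(extras)))
            body <- data.frame(
                LABEL = sprintf("ID%d", seq_len(nrow(df))),
                ID = seq_len(nrow(df)), TRACK_ID = df$track_id,
                QUALITY = 1,
                POSITION_X = sprintf("%.17g", df$x),
                POSITION_Y = sprintf("%.17g", df$y),
                POSITION_Z = sprintf("%.17g", df$z),
                POSITION_T = sprintf("%.17g", df$t * 3600),
                FRAME = frame, stringsAsFactors = FALSE)
            for (e in extras) body[[e]] <- sprintf("%.17g", df[[e]])
            con <- file(p, "w")
            writeLines(paste(hdr, collapse = ","), con)
            writeLines(paste(human, collapse = ","), con)
            writeLines(paste(hdr, collapse = ","), con)  # name row repeat
            writeLines(paste(units, collapse = ","), con)
            utils::write.table(body, con, sep = ",", row.names = FALSE,
                               col.names = FALSE, quote = FALSE)
            close(con)
            p
        },
        mtrackj = {
            p <- file.path(dir, "mtrackj_points.csv")
            tid <- df$track_id
            pid <- stats::ave(seq_along(tid), tid, FUN = seq_along)
            out <- data.frame(TID = tid, PID = pid,
                              x = sprintf("%.17g", df$x),
                              y = sprintf("%.17g", df$y),
                              z = sprintf("%.17g", df$z),
                              Slice = frame + 1L)
            write.csv(out, p, row.names = FALSE, quote = FALSE)
            p
        },
        manual_tracking = {
            if (any(df$z != 0)) {
                stop("manual_tracking is a 2D dialect; table has ",
                     "nonzero z", call. = FALSE)
            }
            p <- file.path(dir, "manual_tracking.csv")
            out <- data.frame(Track = df$track_id, Slice = frame + 1L,
                              X = sprintf("%.17g", df$x),
                              Y = sprintf("%.17g", df$y))
            write.csv(out, p, row.names = FALSE, quote = FALSE)
            p
        })
}
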