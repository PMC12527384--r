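# End-to-end orchestration from a single config (list or YAML file):
# read -> interpolate -> crop -> features -> (optional upstream spatial)
# -> PCA -> DTW -> embed/cluster -> characterize -> (optional downstream
# spatial, region analysis), with a manifest of every artifact.

.defaultConfig <- function() {
    list(
        dt = 1 / 3,
        features = c("speed", "disp2", "disp_d", "disp_l", "persistence"),
        var_threshold = 0.90,
        dtw = list(step = "symmetric2", window = NULL, normalize = FALSE),
        k = NULL,
        seed = 42L,
        umap = list(n_neighbors = 15, min_dist = 0.1),
        cluster_method = "kmeans",
        spatial = list(mode = "none", radius = 30, k_neigh = c(3, 10)),
        out_dir = NULL
    )
}

#' Validate a pipeline run configuration
#'
#' Fills defaults, checks required keys and path existence before any
#' I/O happens. A config is a nested list (or a YAML file with the same
#' structure): `input` (either `simulate: TRUE` plus scene options, or
#' `dialect` + `paths`), `dt`, `features`, `var_threshold`, `dtw`
#' (step/window/normalize), `k`, `seed`, `umap`
#' (n_neighbors/min_dist), `cluster_method`, `spatial` (mode
#' "none"/"upstream"/"downstream", `components` CSV, `radius`,
#' `k_neigh`), `regions` (CSV path), `out_dir`.
#'
#' @param config list or path to a YAML file.
#' @return the validated, default-filled config list.
#' @export
validateConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    def <- .defaultConfig()
    for (nm in names(def)) {
        if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
    }
    if (is.null(config$k)) {
        stop("config error: 'k' (number of behavioral clusters) is ",
             "required", call. = FALSE)
    }
    if (is.null(config$input)) {
        stop("config error: 'input' section is required", call. = FALSE)
    }
    if (is.null(config$out_dir)) {
        stop("config error: 'out_dir' is required", call. = FALSE)
    }
    if (!isTRUE(config$input$simulate)) {
        if (is.null(config$input$dialect) || is.null(config$input$paths)) {
            stop("config error: input needs 'dialect' and 'paths' (or ",
                 "simulate: true)", call. = FALSE)
        }
        missing <- config$input$paths[!file.exists(
            unlist(config$input$paths))]
        if (length(missing)) {
            stop("config error: input path(s) do not exist: ",
                 paste(missing, collapse = ", "), call. = FALSE)
        }
    }
    for (p in c(config$spatial$components, config$regions)) {
        if (!is.null(p) && !file.exists(p)) {
            stop("config error: path does not exist: ", p, call. = FALSE)
        }
    }
    config$seed <- as.integer(config$seed)
    config$k <- as.integer(config$k)
    config
}

.writeArtifact <- function(obj, path, manifest) {
    write.csv(obj, path, row.names = FALSE, quote = FALSE)
    rbind(manifest, data.frame(file = basename(path),
                               md5 = unname(tools::md5sum(path)),
                               bytes = file.size(path),
                               stringsAsFactors = FALSE))
}

#' Run the full behavioral-phenotyping pipeline
#'
#' Executes every stage in order and writes all artifacts plus a
#' manifest (file, md5, bytes) to `out_dir`. Stage outputs are pure
#' functions of (inputs, config, seed), so identical configs give
#' byte-identical manifests. A `run_log.txt` records package version,
#' seed and parameters.
#'
#' @param config list or YAML path, see [validateConfig()].
#' @return list with the in-memory objects (`table`, `tensor`, `pcs`,
#'   `D`, `result`, `summaries`, optional `spatial`, `regions`) and
#'   `manifest` (data.frame).
#' @export
runPipeline <- function(config) {
    cfg <- validateConfig(config)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    logLines <- c(paste("TrackPheno",
                        as.character(utils::packageVersion("TrackPheno"))),
                  paste("seed:", cfg$seed),
                  paste("k:", cfg$k), paste("dt:", cfg$dt))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 "\n  (earlier artifacts in ", cfg$out_dir,
                 " are partial)", call. = FALSE)
        })
    }
    truth <- NULL; regions <- NULL; components <- NULL
    table <- stage("read", {
        if (isTRUE(cfg$input$simulate)) {
            scArgs <- cfg$input$scene %||% list()
            scArgs$seed <- cfg$seed
            sc <- do.call(sceneConfig, scArgs)
            sim <- simulateTracks(sc)
            truth <- sim$truth
            regions <- sim$regions
            if (!is.null(sc$vessels) || length(sc$components)) {
                components <- simulateTME(sc, sim)
            }
            sim$table
        } else {
            switch(cfg$input$dialect,
                imaris = readImarisExport(
                    unlist(cfg$input$paths),
                    edge_column = cfg$input$edge_column,
                    frame_interval = cfg$input$frame_interval %||% cfg$dt),
                trackmate = readTrackMateSpots(
                    cfg$input$paths[[1]],
                    frame_interval = cfg$input$frame_interval %||% cfg$dt),
                mtrackj = readFijiManual(
                    cfg$input$paths[[1]], "mtrackj",
                    frame_interval = cfg$input$frame_interval %||% cfg$dt),
                manual_tracking = readFijiManual(
                    cfg$input$paths[[1]], "manual_tracking",
                    frame_interval = cfg$input$frame_interval %||% cfg$dt),
                stop("unknown input dialect: ", cfg$input$dialect))
        }
    })
    if (!is.null(cfg$regions)) {
        regions <- read.csv(cfg$regions, stringsAsFactors = FALSE)
    }
    if (!is.null(cfg$spatial$components)) {
        components <- readComponents(cfg$spatial$components)
    }
    manifest <- data.frame()
    interp <- stage("interpolate", interpolateToGrid(table, cfg$dt))
    cropped <- stage("crop", suppressMessages(cropCommonLength(interp)))
    tensor <- stage("features", computeKineticFeatures(
        cropped,
        features = intersect(cfg$features,
            c("speed", "disp2", "disp_d", "disp_l", "persistence",
              "invasion")),
        passthrough = intersect(cfg$features, cropped@extraFeatures)))
    spatialTab <- NULL
    if (cfg$spatial$mode != "none" && !is.null(components)) {
        spatialTab <- stage("spatial-features", computeSpatialFeatures(
            cropped, components, radius = cfg$spatial$radius,
            k_neigh = cfg$spatial$k_neigh))
        manifest <- .writeArtifact(
            spatialTab, file.path(cfg$out_dir, "spatial_features.csv"),
            manifest)
        if (cfg$spatial$mode == "upstream") {
            tensor <- stage("spatial-upstream", integrateSpatial(
                "upstream", spatialTab, tensor = tensor,
                features = cfg$spatial$features))
        }
    }
    pcs <- stage("pca", scaleAndPCA(tensor, cfg$var_threshold))
    D <- stage("dtw", crossDistance(
        pcs, step = cfg$dtw$step,
        window = cfg$dtw$window, normalize = isTRUE(cfg$dtw$normalize)))
    result <- stage("cluster", embedAndCluster(
        D, k = cfg$k, seed = cfg$seed,
        n_neighbors = cfg$umap$n_neighbors,
        min_dist = cfg$umap$min_dist, method = cfg$cluster_method))
    summaries <- stage("summarize", summarizeTrackFeatures(tensor))
    result <- stage("characterize",
                    characterizeClusters(result, summaries))
    # artifacts
    manifest <- .writeArtifact(
        data.frame(track_id = rownames(D), D, check.names = FALSE),
        file.path(cfg$out_dir, "distance_matrix.csv"), manifest)
    emb <- data.frame(track_id = trackIds(result),
                      clusterEmbedding(result),
                      cluster = clusterLabels(result))
    manifest <- .writeArtifact(
        emb, file.path(cfg$out_dir, "embedding_clusters.csv"), manifest)
    manifest <- .writeArtifact(
        clusterSummary(result),
        file.path(cfg$out_dir, "cluster_summary.csv"), manifest)
    manifest <- .writeArtifact(
        summaries, file.path(cfg$out_dir, "track_summaries.csv"),
        manifest)
    bp <- file.path(cfg$out_dir, "backprojection.csv")
    stage("backprojection", writeBackprojection(result, cropped, bp))
    manifest <- rbind(manifest, data.frame(
        file = basename(bp), md5 = unname(tools::md5sum(bp)),
        bytes = file.size(bp), stringsAsFactors = FALSE))
    downstream <- NULL
    if (identical(cfg$spatial$mode, "downstream") &&
        !is.null(spatialTab)) {
        downstream <- stage("spatial-downstream", integrateSpatial(
            "downstream", spatialTab, result = result, table = cropped,
            components = components,
            regions = if (!is.null(regions) &&
                          !all(is.na(regions$region_label))) {
                regions
            } else NULL))
        manifest <- .writeArtifact(
            downstream$cluster_summary,
            file.path(cfg$out_dir, "cluster_spatial_summary.csv"),
            manifest)
        if (!is.null(downstream$proximity)) {
            manifest <- .writeArtifact(
                downstream$proximity,
                file.path(cfg$out_dir, "proximity_summary.csv"), manifest)
        }
    }
    regionTests <- NULL; freqs <- NULL
    if (!is.null(regions) && !all(is.na(regions$region_label))) {
        ra <- stage("regions", assignRegions(cropped, regions))
        freqs <- stage("region-frequencies",
                       suppressWarnings(clusterFrequencies(result, ra)))
        manifest <- .writeArtifact(
            freqs, file.path(cfg$out_dir, "region_frequencies.csv"),
            manifest)
        regionTests <- stage("region-tests",
                             suppressWarnings(compareRegions(freqs)))
        if (!is.null(regionTests$anova)) {
            manifest <- .writeArtifact(
                regionTests$anova,
                file.path(cfg$out_dir, "region_tests.csv"), manifest)
        }
    }
    if (!is.null(truth)) {
        manifest <- .writeArtifact(
            truth, file.path(cfg$out_dir, "ground_truth.csv"), manifest)
    }
    manifestPath <- file.path(cfg$out_dir, "manifest.csv")
    write.csv(manifest, manifestPath, row.names = FALSE, quote = FALSE)
    writeLines(c(logLines, paste("artifacts:", nrow(manifest))),
               file.path(cfg$out_dir, "run_log.txt"))
    list(table = table, tensor = tensor, pcs = pcs, D = D,
         result = result, summaries = summaries, spatial = downstream,
         freqs = freqs, region_tests = regionTests, truth = truth,
         manifest = manifest)
}
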