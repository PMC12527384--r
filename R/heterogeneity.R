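# Behavioral-classification engine: standardization + PCA, multivariate
# DTW cross-distance, UMAP embedding, k-means clustering, cluster
# characterization.

#' Standardize features and project timepoints onto principal components
#'
#' Features live on very different scales (µm, µm², unitless ratios), so
#' each feature is standardized to mean 0 / sd 1 over all pooled
#' (track, timepoint) rows before PCA; without this the decomposition is
#' unit-dominated. PCA is fit on the pooled rows and every timepoint is
#' projected. The number of retained components is the smallest m whose
#' cumulative explained variance reaches `var_threshold`.
#'
#' Constant features carry no information and are dropped with a
#' warning.
#'
#' @param tensor a [FeatureTensor-class].
#' @param var_threshold fraction of variance the retained PCs must
#'   explain (default 0.90).
#' @return a [PCSeries-class].
#' @export
scaleAndPCA <- function(tensor, var_threshold = 0.90) {
    stopifnot(is(tensor, "FeatureTensor"),
              var_threshold > 0, var_threshold <= 1)
    v <- tensor@values
    d <- dim(v)
    flat <- matrix(v, nrow = d[1] * d[2], ncol = d[3])
    colnames(flat) <- tensor@featureNames
    sds <- apply(flat, 2, sd)
    constant <- sds < .Machine$double.eps^0.5
    if (any(constant)) {
        warning("dropping constant feature(s): ",
                paste(tensor@featureNames[constant], collapse = ", "),
                call. = FALSE)
        flat <- flat[, !constant, drop = FALSE]
    }
    if (ncol(flat) < 1L) stop("no non-constant features left", call. = FALSE)
    z <- scale(flat)
    pca <- prcomp(z, center = FALSE, scale. = FALSE)
    evr <- pca$sdev^2 / sum(pca$sdev^2)
    nPC <- which(cumsum(evr) >= var_threshold - 1e-12)[1]
    proj <- z %*% pca$rotation[, seq_len(nPC), drop = FALSE]
    arr <- array(proj, dim = c(d[1], d[2], nPC),
                 dimnames = list(tensor@trackIndex, NULL,
                                 paste0("PC", seq_len(nPC))))
    new("PCSeries", values = arr, trackIndex = tensor@trackIndex,
        timeGrid = tensor@timeGrid, explainedVariance = evr,
        nPC = as.integer(nPC), varThreshold = var_threshold)
}

#' Dependent multivariate dynamic time warping distance
#'
#' Aligns two multivariate time series with a single warping path; the
#' local cost between timepoints i and j is the Euclidean norm of
#' `a[i, ] - b[j, ]` across all dimensions, and the cumulative cost is
#' minimized by dynamic programming under the chosen step pattern.
#' `symmetric2` (default) weighs diagonal steps twice, `symmetric1`
#' weighs all steps once. A Sakoe-Chiba band of half-width `window`
#' optionally restricts the warping; `normalize` divides the terminal
#' cost by `nrow(a) + nrow(b)`.
#'
#' @param a,b numeric matrices (timepoints x dimensions) with equal
#'   dimension count; plain vectors are treated as single-dimension
#'   series.
#' @param step "symmetric2" or "symmetric1".
#' @param window integer band half-width, or NULL for unconstrained.
#'   Must be at least `abs(nrow(a) - nrow(b))` for a path to exist.
#' @param normalize logical; divide by the summed series lengths.
#' @return non-negative scalar distance.
#' @examples
#' x <- cbind(sin(1:10), cos(1:10))
#' dtwDistance(x, x)                      # 0
#' dtwDistance(matrix(0), matrix(5))      # 5
#' @export
dtwDistance <- function(a, b, step = c("symmetric2", "symmetric1"),
                        window = NULL, normalize = FALSE) {
    step <- match.arg(step)
    if (is.vector(a)) a <- matrix(a, ncol = 1)
    if (is.vector(b)) b <- matrix(b, ncol = 1)
    a <- as.matrix(a); b <- as.matrix(b)
    if (nrow(a) == 0L || nrow(b) == 0L) stop("empty series", call. = FALSE)
    if (ncol(a) != ncol(b)) {
        stop("series dimensionality differs: ", ncol(a), " vs ", ncol(b),
             call. = FALSE)
    }
    w <- if (is.null(window)) -1L else as.integer(window)
    if (w >= 0L && w < abs(nrow(a) - nrow(b))) {
        stop("window ", w, " smaller than the length difference ",
             abs(nrow(a) - nrow(b)), "; no warping path exists",
             call. = FALSE)
    }
    dtw_cost_cpp(a, b, if (step == "symmetric2") 2L else 1L, w,
                 isTRUE(normalize))
}

#' DTW cross-distance matrix over all tracks
#'
#' Computes `D[i, j] = dtwDistance(track_i, track_j)` on the
#' per-timepoint PC series for every unordered pair (i < j, mirrored),
#' with zeros on the diagonal.
#'
#' @param pcs a [PCSeries-class] (or a [FeatureTensor-class], if
#'   clustering on raw features is wanted).
#' @inheritParams dtwDistance
#' @return symmetric n x n matrix with track ids as dimnames.
#' @export
crossDistance <- function(pcs, step = c("symmetric2", "symmetric1"),
                          window = NULL, normalize = FALSE) {
    step <- match.arg(step)
    stopifnot(is(pcs, "PCSeries") || is(pcs, "FeatureTensor"))
    v <- tensorValues(pcs)
    if (dim(v)[1] < 2L) stop("need at least 2 tracks", call. = FALSE)
    w <- if (is.null(window)) -1L else as.integer(window)
    D <- cross_dtw_cpp(as.numeric(v), dim(v),
                       if (step == "symmetric2") 2L else 1L, w,
                       isTRUE(normalize))
    dimnames(D) <- list(trackIds(pcs), trackIds(pcs))
    D
}

#' Embed the cross-distance matrix and cluster tracks
#'
#' Runs UMAP in precomputed-distance mode on the DTW cross-distance
#' matrix (delegated to \pkg{uwot}, single-threaded for reproducibility)
#' and partitions the 2D embedding with k-means (multiple restarts).
#' Alternatively, `method = "pam"` clusters the distance matrix directly
#' with partitioning around medoids, skipping the embedding's influence
#' on the labels (an embedding is still computed for plotting).
#'
#' All seeds and hyperparameters are recorded in the result.
#'
#' @param D symmetric distance matrix from [crossDistance()].
#' @param k number of clusters, `2 <= k < n`. The cluster count is a user
#'   choice; see [silhouetteDiagnostic()] for guidance.
#' @param seed integer seed controlling UMAP and k-means.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param method "kmeans" (on the embedding) or "pam" (on D).
#' @param nstart k-means restarts.
#' @return a [ClusterResult-class].
#' @export
embedAndCluster <- function(D, k, seed = 42L, n_neighbors = 15,
                            min_dist = 0.1,
                            method = c("kmeans", "pam"), nstart = 25L) {
    method <- match.arg(method)
    stopifnot(is.matrix(D), nrow(D) == ncol(D))
    n <- nrow(D)
    if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric", call. = FALSE)
    if (k < 2L || k >= n) {
        stop("k must satisfy 2 <= k < n (n = ", n, ")", call. = FALSE)
    }
    seed <- as.integer(seed)
    set.seed(seed)
    emb <- uwot::umap(as.dist(D),
                      n_neighbors = min(n_neighbors, n - 1),
                      min_dist = min_dist, n_components = 2,
                      n_threads = 1, n_sgd_threads = 0)
    colnames(emb) <- c("UMAP1", "UMAP2")
    set.seed(seed + 1L)
    if (method == "kmeans") {
        labels <- kmeans(emb, centers = k, nstart = nstart,
                         iter.max = 100)$cluster
    } else {
        labels <- cluster::pam(as.dist(D), k = k, cluster.only = TRUE)
    }
    new("ClusterResult",
        trackIndex = rownames(D) %||% as.character(seq_len(n)),
        embedding = emb, labels = as.integer(labels), k = as.integer(k),
        seed = seed,
        params = list(method = method, n_neighbors = n_neighbors,
                      min_dist = min_dist, nstart = nstart))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average silhouette width across candidate cluster counts
#'
#' Diagnostic only -- the cluster count stays a user choice and is never
#' auto-applied.
#'
#' @param D distance matrix.
#' @param ks integer vector of candidate k.
#' @inheritParams embedAndCluster
#' @return data.frame with columns `k` and `avg_silhouette`.
#' @export
silhouetteDiagnostic <- function(D, ks = 2:10, seed = 42L) {
    ks <- ks[ks >= 2 & ks < nrow(D)]
    res <- vapply(ks, function(k) {
        r <- embedAndCluster(D, k, seed = seed)
        mean(cluster::silhouette(r@labels, as.dist(D))[, "sil_width"])
    }, numeric(1))
    data.frame(k = ks, avg_silhouette = res)
}

#' Characterize clusters by their average feature values
#'
#' For every cluster and track-level feature the mean over member tracks
#' is computed; per feature a one-way ANOVA tests for differences across
#' clusters. For heatmap display the cluster means are min-max rescaled
#' per feature to \[0, 1\] (a feature constant across clusters rescales
#' to 0); the raw means are retained alongside.
#'
#' @param result a [ClusterResult-class].
#' @param track_summaries per-track table from
#'   [summarizeTrackFeatures()] (column `track_id` plus numeric feature
#'   columns); labels must cover all summarized tracks.
#' @return the [ClusterResult-class] with its `summary` slot filled: one
#'   row per (cluster, feature) with `mean`, `rescaled`, `anova_p`.
#' @export
characterizeClusters <- function(result, track_summaries) {
    stopifnot(is(result, "ClusterResult"),
              "track_id" %in% names(track_summaries))
    lab <- clusterLabels(result)
    missing <- setdiff(track_summaries$track_id, names(lab))
    if (length(missing)) {
        stop("tracks without a cluster label: ",
             paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    cl <- lab[track_summaries$track_id]
    feats <- setdiff(names(track_summaries), "track_id")
    rows <- list()
    for (f in feats) {
        v <- track_summaries[[f]]
        means <- tapply(v, cl, mean)
        rng <- max(means) - min(means)
        resc <- if (rng > 0) (means - min(means)) / rng else means * 0
        counts <- table(cl)
        p <- if (any(counts < 2)) {
            warning("cluster with < 2 tracks; ANOVA skipped for '", f,
                    "'", call. = FALSE)
            NA_real_
        } else {
            oneWayAnova(v, cl)$p
        }
        rows[[f]] <- data.frame(cluster = as.integer(names(means)),
                                feature = f, mean = as.numeric(means),
                                rescaled = as.numeric(resc), anova_p = p,
                                stringsAsFactors = FALSE)
    }
    result@summary <- do.call(rbind, c(rows, make.row.names = FALSE))
    result
}

#' Plot the cluster-by-feature heatmap
#'
#' Renders the min-max rescaled per-cluster feature means computed by
#' [characterizeClusters()] (requires \pkg{pheatmap}).
#'
#' @param result a characterized [ClusterResult-class].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotClusterHeatmap <- function(result, ...) {
    s <- clusterSummary(result)
    if (!nrow(s)) stop("run characterizeClusters() first", call. = FALSE)
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
        stop("pheatmap is required for plotting", call. = FALSE)
    }
    m <- tapply(s$rescaled, list(s$cluster, s$feature), identity)
    invisible(pheatmap::pheatmap(m, cluster_rows = FALSE,
                                 cluster_cols = FALSE, ...))
}
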