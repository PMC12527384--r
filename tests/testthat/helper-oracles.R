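# Independent oracles and small fixture builders shared across tests.
# These re-derive expected values by different code paths (recursive /
# brute-force / base R) and must stay independent of the package
# implementations they check.

# DTW reference: top-down recursion over all monotone warping paths
# (memoized; explores the same path space as exhaustive enumeration).
dtwOracle <- function(a, b, step = "symmetric2", window = NULL,
                      normalize = FALSE) {
    a <- as.matrix(a); b <- as.matrix(b)
    memo <- new.env(parent = emptyenv())
    d <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
    rec <- function(i, j) {
        if (!is.null(window) && abs(i - j) > window) return(Inf)
        key <- paste0(i, "_", j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        val <- if (i == 1 && j == 1) {
            d(1, 1)
        } else {
            dij <- d(i, j)
            w <- if (step == "symmetric2") 2 else 1
            min(if (i > 1) rec(i - 1, j) + dij else Inf,
                if (j > 1) rec(i, j - 1) + dij else Inf,
                if (i > 1 && j > 1) rec(i - 1, j - 1) + w * dij else Inf)
        }
        memo[[key]] <- val
        val
    }
    out <- rec(nrow(a), nrow(b))
    if (normalize && is.finite(out)) out / (nrow(a) + nrow(b)) else out
}

# O(n^2) spatial brute forces
bruteKnnMean <- function(cells, k) {
    cells <- as.matrix(cells)
    if (ncol(cells) == 2) cells <- cbind(cells, 0)
    n <- nrow(cells)
    vapply(seq_len(n), function(i) {
        d <- sqrt(colSums((t(cells[-i, , drop = FALSE]) - cells[i, ])^2))
        if (length(d) < k) NA_real_ else mean(sort(d)[seq_len(k)])
    }, numeric(1))
}

bruteCountRadius <- function(cells, pts, radius) {
    cells <- as.matrix(cells)
    if (ncol(cells) == 2) cells <- cbind(cells, 0)
    vapply(seq_len(nrow(cells)), function(i) {
        d <- sqrt(colSums((t(pts) - cells[i, ])^2))
        sum(d <= radius)
    }, numeric(1))
}

bruteMinDist <- function(cells, pts) {
    cells <- as.matrix(cells)
    if (ncol(cells) == 2) cells <- cbind(cells, 0)
    vapply(seq_len(nrow(cells)), function(i) {
        min(sqrt(colSums((t(pts) - cells[i, ])^2)))
    }, numeric(1))
}

# minimal single-track data.frame
trackDf <- function(t, x, y = 0, z = 0, dist_to_edge = NULL,
                    track_id = "1", mouse_id = "m1", position_id = "p1") {
    df <- data.frame(mouse_id = mouse_id, position_id = position_id,
                     track_id = track_id, t = t, x = x, y = y, z = z,
                     stringsAsFactors = FALSE)
    if (!is.null(dist_to_edge)) df$dist_to_edge <- dist_to_edge
    df
}

globalIdsOf <- function(truth) {
    paste(truth$mouse_id, truth$position_id, truth$track_id, sep = ".")
}

# a ClusterResult carrying the simulator's planted archetypes as labels
truthClusterResult <- function(sim) {
    lab <- as.integer(factor(sim$truth$archetype))
    new("ClusterResult", trackIndex = globalIdsOf(sim$truth),
        embedding = matrix(0, length(lab), 2), labels = lab,
        k = length(unique(lab)), seed = sim$seed, params = list())
}

archetypeOf <- function(sim) {
    setNames(sim$truth$archetype, globalIdsOf(sim$truth))
}

# random rigid motion (rotation + translation) for invariance checks
randomRigid <- function() {
    m <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(R = q, shift = rnorm(3, sd = 50))
}
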