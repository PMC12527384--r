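# PCA component selection, DTW, cross-distance, clustering and cluster
# characterization.

randomTensor <- function(n, L, f, seed = 1, gen = rnorm) {
    set.seed(seed)
    new("FeatureTensor",
        values = array(gen(n * L * f), c(n, L, f),
                       dimnames = list(paste0("t", seq_len(n)), NULL,
                                       paste0("f", seq_len(f)))),
        trackIndex = paste0("t", seq_len(n)),
        timeGrid = seq(0, by = 1 / 3, length.out = L),
        featureNames = paste0("f", seq_len(f)),
        provenance = setNames(rep("computed", f), paste0("f", seq_len(f))))
}

test_that("PC count is the minimal one reaching the variance threshold", {
    # 5 independent equal-variance features: each PC carries ~20%
    tensor <- randomTensor(200, 10, 5, seed = 11)
    pcs <- scaleAndPCA(tensor, var_threshold = 0.90)
    expect_equal(pcs@nPC, 5L)
    expect_equal(sum(explainedVariance(pcs)), 1, tolerance = 1e-9)

    # exact linear dependence collapses to one informative PC
    t2 <- randomTensor(50, 6, 2, seed = 12)
    t2@values[, , 2] <- 2 * t2@values[, , 1]
    pcs2 <- scaleAndPCA(t2, var_threshold = 0.90)
    expect_equal(pcs2@nPC, 1L)
    expect_lt(explainedVariance(pcs2)[2], 1e-12)

    # threshold 1.0 retains full rank
    pcs3 <- scaleAndPCA(tensor, var_threshold = 1.0)
    expect_equal(pcs3@nPC, 5L)

    # constant feature dropped with a warning
    t3 <- randomTensor(30, 5, 3, seed = 13)
    t3@values[, , 3] <- 7
    expect_warning(pcs4 <- scaleAndPCA(t3), "constant")
    expect_length(explainedVariance(pcs4), 2L)
})

test_that("DTW distance agrees with the recursive path oracle", {
    expect_equal(dtwDistance(matrix(0), matrix(5)), 5)
    x <- cbind(sin(1:10), cos(1:10))
    expect_equal(dtwDistance(x, x), 0)
    expect_error(dtwDistance(matrix(0, 1, 1), matrix(0, 1, 2)),
                 "dimensionality")
    expect_error(dtwDistance(matrix(0, 0, 1), matrix(0, 1, 1)), "empty")

    set.seed(21)
    for (rep in 1:50) {
        na <- sample(2:10, 1); nb <- sample(2:10, 1)
        d <- sample(1:4, 1)
        a <- matrix(rnorm(na * d), na, d)
        b <- matrix(rnorm(nb * d), nb, d)
        step <- sample(c("symmetric1", "symmetric2"), 1)
        norm <- sample(c(TRUE, FALSE), 1)
        expect_equal(dtwDistance(a, b, step = step, normalize = norm),
                     dtwOracle(a, b, step = step, normalize = norm),
                     tolerance = 1e-9)
        # symmetry and non-negativity
        expect_equal(dtwDistance(a, b, step = step),
                     dtwDistance(b, a, step = step), tolerance = 1e-9)
        expect_gte(dtwDistance(a, b), 0)
    }
})

test_that("a Sakoe-Chiba window never decreases the distance", {
    set.seed(22)
    for (rep in 1:20) {
        n <- sample(4:9, 1)
        a <- matrix(rnorm(n * 2), n, 2)
        b <- matrix(rnorm(n * 2), n, 2)
        free <- dtwDistance(a, b)
        for (w in c(1, 2, 3)) {
            dw <- dtwDistance(a, b, window = w)
            expect_gte(dw + 1e-12, free)
            expect_equal(dw, dtwOracle(a, b, window = w), tolerance = 1e-9)
        }
    }
    expect_error(dtwDistance(matrix(0, 8, 1), matrix(0, 2, 1), window = 1),
                 "window")
})

test_that("cross-distance matrix mirrors per-pair DTW calls", {
    tensor <- randomTensor(8, 6, 3, seed = 23)
    pcs <- scaleAndPCA(tensor, var_threshold = 1.0)
    D <- crossDistance(pcs)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    v <- tensorValues(pcs)
    for (i in 1:7) for (j in (i + 1):8) {
        expect_equal(D[i, j],
                     dtwDistance(v[i, , ], v[j, , ]), tolerance = 1e-9)
    }
    # duplicated series are at distance zero
    t2 <- randomTensor(3, 6, 2, seed = 24)
    t2@values[2, , ] <- t2@values[1, , ]
    D2 <- crossDistance(t2)
    expect_equal(D2[1, 2], 0)
})

test_that("well-separated groups are recovered and runs are deterministic", {
    set.seed(31)
    n <- 60
    centers <- c(0, 30, 90)
    truth <- rep(1:3, each = n / 3)
    vals <- array(0, c(n, 8, 2))
    for (i in seq_len(n)) {
        vals[i, , 1] <- centers[truth[i]] + rnorm(8)
        vals[i, , 2] <- -centers[truth[i]] + rnorm(8)
    }
    tensor <- new("FeatureTensor", values = vals,
                  trackIndex = paste0("t", 1:n),
                  timeGrid = seq(0, by = 1 / 3, length.out = 8),
                  featureNames = c("a", "b"),
                  provenance = c(a = "computed", b = "computed"))
    D <- crossDistance(scaleAndPCA(tensor))
    res <- embedAndCluster(D, k = 3, seed = 42)
    expect_gte(mclust::adjustedRandIndex(clusterLabels(res), truth), 0.9)

    res2 <- embedAndCluster(D, k = 3, seed = 42)
    expect_identical(clusterLabels(res2), clusterLabels(res))
    expect_identical(clusterEmbedding(res2), clusterEmbedding(res))

    # PAM route clusters the distance matrix directly
    resPam <- embedAndCluster(D, k = 3, seed = 42, method = "pam")
    expect_gte(mclust::adjustedRandIndex(clusterLabels(resPam), truth), 0.9)

    expect_error(embedAndCluster(D, k = 1), "k must")
    expect_error(embedAndCluster(D, k = n), "k must")
})

test_that("cluster characterization rescales means and tests features", {
    res <- new("ClusterResult", trackIndex = paste0("t", 1:4),
               embedding = matrix(0, 4, 2), labels = c(1L, 1L, 2L, 2L),
               k = 2L, seed = 1L, params = list())
    summ <- data.frame(track_id = paste0("t", 1:4),
                       mean_speed = c(1, 1, 3, 3),
                       flat = c(2, 2, 2, 2))
    out <- suppressWarnings(clusterSummary(
        characterizeClusters(res, summ)))
    sp <- out[out$feature == "mean_speed", ]
    expect_equal(sp$mean, c(1, 3))
    expect_equal(sp$rescaled, c(0, 1))
    fl <- out[out$feature == "flat", ]
    expect_equal(fl$rescaled, c(0, 0))

    # ANOVA p matches the base R fit on the same grouping
    set.seed(32)
    summ2 <- data.frame(track_id = paste0("t", 1:4),
                        v = rnorm(4, mean = c(0, 0, 2, 2)))
    out2 <- clusterSummary(characterizeClusters(res, summ2))
    pOracle <- anova(lm(summ2$v ~ factor(res@labels)))$`Pr(>F)`[1]
    expect_equal(unique(out2$anova_p), pOracle, tolerance = 1e-9)

    expect_error(characterizeClusters(
        res, data.frame(track_id = "zz", v = 1)), "without a cluster")
})

test_that("silhouette diagnostic reports widths without choosing k", {
    tensor <- randomTensor(30, 6, 2, seed = 33)
    D <- crossDistance(scaleAndPCA(tensor))
    sil <- silhouetteDiagnostic(D, ks = 2:4, seed = 1)
    expect_equal(sil$k, 2:4)
    expect_true(all(is.finite(sil$avg_silhouette)))
})
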