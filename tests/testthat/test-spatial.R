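# Spatial statistics against brute force, proximity rules, and the two
# integration routes.

test_that("kNN mean distance matches geometry and brute force", {
    cells <- cbind(0:3, 0, 0)
    d <- knnMeanDistance(cells, k = 3)
    expect_equal(d[1], (1 + 2 + 3) / 3)
    expect_equal(d[2], (1 + 1 + 2) / 3)

    expect_true(is.na(knnMeanDistance(matrix(c(0, 0, 0), 1), k = 1)))

    set.seed(51)
    pts <- matrix(runif(300 * 3, 0, 100), ncol = 3)
    expect_equal(knnMeanDistance(pts, 10), bruteKnnMean(pts, 10),
                 tolerance = 1e-9)
    expect_equal(knnMeanDistance(pts, 3), bruteKnnMean(pts, 3),
                 tolerance = 1e-9)
})

test_that("radius counts are boundary-inclusive and match brute force", {
    comp <- TMEComponentSet("SR101",
                            rbind(c(10, 0, 0), c(0, 30, 0), c(0, 0, 31)))
    expect_equal(countWithinRadius(matrix(0, 1, 3), comp, radius = 30), 2L)

    set.seed(52)
    cells <- matrix(runif(200 * 3, 0, 100), ncol = 3)
    pts <- matrix(runif(400 * 3, 0, 100), ncol = 3)
    cp <- TMEComponentSet("X", pts)
    expect_equal(countWithinRadius(cells, cp, 30),
                 as.integer(bruteCountRadius(cells, pts, 30)))

    expect_warning(
        z <- countWithinRadius(cells,
                               TMEComponentSet("E", matrix(0, 0, 3))),
        "empty")
    expect_true(all(z == 0))
})

test_that("minimum component distance matches brute force", {
    cp <- TMEComponentSet("BV", rbind(c(3, 4, 0), c(10, 10, 10)))
    expect_equal(minComponentDistance(matrix(0, 1, 3), cp), 5)
    expect_equal(minComponentDistance(matrix(c(3, 4, 0), 1), cp), 0)

    set.seed(53)
    cells <- matrix(runif(200 * 3, 0, 100), ncol = 3)
    pts <- matrix(runif(300 * 3, 0, 100), ncol = 3)
    expect_equal(minComponentDistance(cells, TMEComponentSet("X", pts)),
                 bruteMinDist(cells, pts), tolerance = 1e-9)

    expect_warning(
        z <- minComponentDistance(cells,
                                  TMEComponentSet("E", matrix(0, 0, 3))),
        "empty")
    expect_true(all(is.na(z)))
})

test_that("proximity thresholds depend on how objects were rendered", {
    expect_true(classifyProximity(14.9, "surface_sample"))
    expect_true(classifyProximity(15.0, "surface_sample"))  # inclusive
    expect_false(classifyProximity(15.1, "surface_sample"))
    expect_true(classifyProximity(3.0, "spot"))
    expect_false(classifyProximity(3.1, "spot"))
    expect_false(classifyProximity(NA_real_, "spot"))
    expect_true(classifyProximity(9, "spot", threshold = 10))
})

test_that("spatial features are invariant under joint rigid motion", {
    set.seed(54)
    cells <- matrix(runif(60 * 3, 0, 80), ncol = 3)
    pts <- matrix(runif(120 * 3, 0, 80), ncol = 3)
    cp <- TMEComponentSet("X", pts)
    rig <- randomRigid()
    cells2 <- sweep(cells %*% t(rig$R), 2, -rig$shift)
    cp2 <- TMEComponentSet("X", sweep(pts %*% t(rig$R), 2, -rig$shift))
    expect_equal(knnMeanDistance(cells2, 5), knnMeanDistance(cells, 5),
                 tolerance = 1e-9)
    expect_equal(countWithinRadius(cells2, cp2, 25),
                 countWithinRadius(cells, cp, 25))
    expect_equal(minComponentDistance(cells2, cp2),
                 minComponentDistance(cells, cp), tolerance = 1e-9)
})

test_that("radius growth and extra points act monotonically", {
    set.seed(55)
    cells <- matrix(runif(40 * 3, 0, 60), ncol = 3)
    pts <- matrix(runif(80 * 3, 0, 60), ncol = 3)
    cp <- TMEComponentSet("X", pts)
    n1 <- countWithinRadius(cells, cp, 20)
    n2 <- countWithinRadius(cells, cp, 35)
    expect_true(all(n2 >= n1))
    more <- TMEComponentSet("X", rbind(pts,
                                       matrix(runif(30 * 3, 0, 60), ncol = 3)))
    expect_true(all(minComponentDistance(cells, more) <=
                    minComponentDistance(cells, cp) + 1e-12))
})

test_that("upstream integration appends aligned spatial features", {
    sim <- simulateTracks(sceneConfig(
        archetypePresets("easy", 4L), n_timepoints = 6,
        dropout_rate = 0, seed = 56,
        components = list(SR101 = list(n = 400, kind = "surface_sample"))))
    comps <- simulateTME(sceneConfig(
        archetypePresets("easy", 4L), n_timepoints = 6, dropout_rate = 0,
        seed = 56,
        components = list(SR101 = list(n = 400, kind = "surface_sample"))),
        sim)
    crop <- suppressMessages(cropCommonLength(
        interpolateToGrid(sim$table, 1 / 3)))
    tensor <- computeKineticFeatures(crop, features = c("speed", "disp_d"))
    sp <- computeSpatialFeatures(crop, comps, k_neigh = 3)

    aug <- integrateSpatial("upstream", sp, tensor = tensor,
                            features = c("n_SR101", "min_SR101"))
    expect_equal(featureNames(aug),
                 c("speed", "disp_d", "n_SR101", "min_SR101"))
    # values land at the right (track, timepoint) cells
    i <- 5
    gid <- paste(sp$mouse_id, sp$position_id, sp$track_id, sep = ".")
    row <- which(gid == trackIds(aug)[i] & abs(sp$t - min(sp$t[gid ==
        trackIds(aug)[i]]) - timeGrid(aug)[3]) < 1e-9)
    expect_equal(tensorValues(aug)[i, 3, "min_SR101"], sp$min_SR101[row])

    # zero selected features: unchanged
    expect_identical(
        integrateSpatial("upstream", sp, tensor = tensor,
                         features = character()),
        tensor)

    # per-track-only features cannot be time-aligned
    spBad <- sp[sp$t == min(sp$t), ]
    expect_error(integrateSpatial("upstream", spBad, tensor = tensor,
                                  features = "min_SR101"),
                 "time alignment")
})

test_that("downstream integration recovers planted vessel tropism", {
    sc <- sceneConfig(archetypePresets("easy", 25L),
                      vessels = list(n = 25, along_archetype = "invading"),
                      seed = 57)
    sim <- simulateTracks(sc)
    comps <- simulateTME(sc, sim)
    crop <- suppressMessages(cropCommonLength(
        interpolateToGrid(sim$table, 1 / 3)))
    sp <- suppressWarnings(computeSpatialFeatures(crop, comps,
                                                  k_neigh = c(3, 10)))
    res <- truthClusterResult(sim)
    down <- suppressWarnings(suppressMessages(
        integrateSpatial("downstream", sp, result = res, table = crop,
                         components = comps)))
    bv <- down$cluster_summary[down$cluster_summary$feature == "min_BV", ]
    lev <- levels(factor(sim$truth$archetype))
    invadingCluster <- which(lev == "invading")
    expect_equal(bv$cluster[which.min(bv$mean)], invadingCluster)
    expect_lt(bv$anova_p[1], 0.001)

    # proximity percentages stay within [0, 100] and cover all clusters
    pr <- down$proximity[down$proximity$component == "BV", ]
    expect_true(all(pr$pct_close >= 0 & pr$pct_close <= 100))
    expect_setequal(unique(pr$cluster), seq_len(res@k))
})

test_that("close and not-close cells partition each position", {
    set.seed(58)
    cells <- matrix(runif(50 * 3, 0, 40), ncol = 3)
    cp <- TMEComponentSet("BV", matrix(runif(60 * 3, 0, 40), ncol = 3),
                          objectKind = "spot")
    close <- classifyProximity(minComponentDistance(cells, cp), "spot")
    expect_equal(sum(close) + sum(!close), nrow(cells))
})
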