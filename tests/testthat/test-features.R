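# Interpolation, cropping and kinetic feature extraction.

test_that("linear interpolation fills missing grid points exactly", {
    # linear signal: interior point recovered exactly
    tab <- TrackTable(trackDf(t = c(0, 1, 3), x = c(0, 1, 3)))
    out <- trackData(interpolateToGrid(tab, dt = 1))
    expect_equal(out$t, 0:3)
    expect_equal(out$x, 0:3)

    # no missing frames: identity
    tab2 <- TrackTable(trackDf(t = 0:4, x = sin(0:4), y = cos(0:4)))
    out2 <- trackData(interpolateToGrid(tab2, dt = 1))
    expect_equal(out2$x, sin(0:4), tolerance = 1e-12)
    expect_equal(out2$y, cos(0:4), tolerance = 1e-12)

    # quadratic motion gets the LINEAR estimate, by design
    tab3 <- TrackTable(trackDf(t = c(0, 2), x = c(0, 4)))  # x = t^2
    out3 <- trackData(interpolateToGrid(tab3, dt = 1))
    expect_equal(out3$x[2], 2)  # chord midpoint, not 1

    # dist_to_edge and extra features are interpolated too
    df <- trackDf(t = c(0, 2), x = c(0, 2), dist_to_edge = c(10, 14))
    df$AREA <- c(100, 120)
    out4 <- trackData(interpolateToGrid(
        TrackTable(df, extraFeatures = "AREA"), dt = 1))
    expect_equal(out4$dist_to_edge, c(10, 12, 14))
    expect_equal(out4$AREA, c(100, 110, 120))
})

test_that("tracks spanning less than dt are dropped with a warning", {
    df <- rbind(trackDf(t = c(0, 0.1), x = c(0, 1), track_id = "short"),
                trackDf(t = 0:3, x = 0:3, track_id = "long"))
    expect_warning(out <- interpolateToGrid(TrackTable(df), dt = 1),
                   "dropped")
    expect_equal(trackIds(out), "m1.p1.long")
})

test_that("cropping truncates every track to the minimal common length", {
    df <- rbind(trackDf(t = 0:7, x = 0:7, track_id = "a"),
                trackDf(t = 0:9, x = 0:9, track_id = "b"),
                trackDf(t = 0:13, x = 0:13, track_id = "c"))
    out <- suppressMessages(cropCommonLength(TrackTable(df)))
    lens <- table(trackData(out)$track_id)
    expect_true(all(lens == 8))
    expect_equal(attr(trackData(out), "croppedLength"), 8L)

    # equal lengths: identity
    df2 <- rbind(trackDf(t = 0:4, x = 0:4, track_id = "a"),
                 trackDf(t = 0:4, x = 5:9, track_id = "b"))
    out2 <- suppressMessages(cropCommonLength(TrackTable(df2)))
    expect_equal(trackData(out2)$x, trackData(TrackTable(df2))$x)

    # L < 3 is an actionable error
    df3 <- rbind(trackDf(t = 0:1, x = 0:1, track_id = "a"),
                 trackDf(t = 0:4, x = 0:4, track_id = "b"))
    expect_error(cropCommonLength(TrackTable(df3)), "minimum track length")
})

test_that("kinetic features match hand-computed geometry", {
    # static track: all kinetics zero
    tab <- TrackTable(trackDf(t = (0:4) / 3, x = 1, y = 2, z = 3))
    v <- tensorValues(computeKineticFeatures(
        tab, features = c("speed", "disp2", "disp_d", "disp_l",
                          "persistence")))
    expect_true(all(v == 0))

    # straight line, 2 um steps at dt = 1/3 h: speed 6 um/h, persistence 1
    tab2 <- TrackTable(trackDf(t = (0:4) / 3, x = 2 * (0:4)))
    t2 <- computeKineticFeatures(tab2, features = c("speed", "persistence"))
    v2 <- tensorValues(t2)
    expect_equal(as.numeric(v2[1, -1, "speed"]), rep(6, 4))
    expect_equal(as.numeric(v2[1, -1, "persistence"]), rep(1, 4))
    expect_equal(as.numeric(v2[1, 1, c("speed", "persistence")]), c(0, 0))

    # L-shaped path: (0,0,0) -> (1,0,0) -> (1,1,0), dt = 1
    tab3 <- TrackTable(trackDf(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1)))
    v3 <- tensorValues(computeKineticFeatures(
        tab3, features = c("disp2", "disp_d", "disp_l", "persistence")))
    expect_equal(as.numeric(v3[1, 3, "disp_l"]), 2)
    expect_equal(as.numeric(v3[1, 3, "disp_d"]), sqrt(2))
    expect_equal(as.numeric(v3[1, 3, "persistence"]), sqrt(2) / 2)
    expect_equal(as.numeric(v3[1, , "disp2"]), c(0, 1, 2))

    # invasion velocity: backward difference of dist_to_edge
    tab4 <- TrackTable(trackDf(t = 0:2, x = c(5, 8, 4), y = 0,
                               dist_to_edge = c(5, 8, 4)))
    v4 <- tensorValues(computeKineticFeatures(tab4, features = "invasion"))
    expect_equal(as.numeric(v4[1, , "invasion"]), c(0, 3, -4))

    expect_error(
        computeKineticFeatures(TrackTable(trackDf(t = 0:2, x = 0:2)),
                               features = "invasion"),
        "dist_to_edge")
})

test_that("kinetic invariants hold on random tracks", {
    set.seed(101)
    for (rep in 1:10) {
        n <- sample(4:12, 1)
        df <- trackDf(t = seq(0, by = 1 / 3, length.out = n),
                      x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                      z = cumsum(rnorm(n)))
        tab <- TrackTable(df)
        v <- tensorValues(computeKineticFeatures(
            tab, features = c("speed", "disp2", "disp_d", "disp_l",
                              "persistence")))
        expect_true(all(v[1, , "speed"] >= 0))
        expect_true(all(v[1, , "disp_l"] - v[1, , "disp_d"] >= -1e-9))
        expect_true(all(v[1, , "persistence"] >= 0 &
                        v[1, , "persistence"] <= 1 + 1e-12))
        expect_true(all(diff(v[1, , "disp_l"]) >= -1e-12))

        # translation invariance
        df2 <- df; df2$x <- df$x + 37; df2$y <- df$y - 11; df2$z <- df$z + 5
        v2 <- tensorValues(computeKineticFeatures(
            TrackTable(df2), features = c("speed", "disp2", "disp_d",
                                          "disp_l", "persistence")))
        expect_equal(v2, v, tolerance = 1e-9, ignore_attr = TRUE)

        # rotation invariance (kinetics are edge-free here)
        rig <- randomRigid()
        p <- as.matrix(df[, c("x", "y", "z")]) %*% t(rig$R)
        df3 <- df; df3$x <- p[, 1]; df3$y <- p[, 2]; df3$z <- p[, 3]
        v3 <- tensorValues(computeKineticFeatures(
            TrackTable(df3), features = c("speed", "disp2", "disp_d",
                                          "disp_l", "persistence")))
        expect_equal(v3, v, tolerance = 1e-8, ignore_attr = TRUE)
    }
})

test_that("the long-format tensor dump is faithful", {
    tab <- TrackTable(trackDf(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1)))
    tensor <- computeKineticFeatures(tab, features = c("speed", "disp_l"))
    p <- withr::local_tempfile(fileext = ".csv")
    writeTensorLong(tensor, p)
    long <- read.csv(p)
    expect_equal(nrow(long), 3 * 2)
    expect_equal(long$value[long$feature == "disp_l" & long$t == 2], 2)
    expect_equal(long$value[long$feature == "speed" & long$t == 0], 0)
})

test_that("track summaries give time means and ranges", {
    df <- rbind(trackDf(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1),
                        track_id = "L"),
                trackDf(t = 0:2, x = 0, track_id = "still"))
    tensor <- computeKineticFeatures(
        TrackTable(df), features = c("disp2", "speed"))
    s <- summarizeTrackFeatures(tensor)
    expect_equal(s$mean_disp2[s$track_id == "m1.p1.L"], (0 + 1 + 2) / 3)
    expect_equal(s$mean_disp2[s$track_id == "m1.p1.still"], 0)
    expect_equal(s$disp2_range[s$track_id == "m1.p1.L"], 2)
    expect_equal(s$speed_range[s$track_id == "m1.p1.still"], 0)

    # arithmetic forced: {1, 4, 2} -> mean 7/3, range 3
    fake <- new("FeatureTensor",
                values = array(c(1, 4, 2), c(1, 3, 1),
                               dimnames = list("t1", NULL, "f")),
                trackIndex = "t1", timeGrid = 0:2, featureNames = "f",
                provenance = c(f = "computed"))
    s2 <- summarizeTrackFeatures(fake)
    expect_equal(s2$mean_f, 7 / 3)
    expect_equal(s2$f_range, 3)
})
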