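# Region assignment, cluster-frequency tables and region comparisons.

twoPosTable <- function() {
    df <- rbind(
        trackDf(t = 0:3, x = 0:3, track_id = "1", position_id = "p1"),
        trackDf(t = 0:3, x = 4:7, track_id = "2", position_id = "p1"),
        trackDf(t = 0:3, x = 0:3, track_id = "1", position_id = "p2"))
    TrackTable(df)
}

test_that("tracks inherit position labels; cell labels take precedence", {
    tab <- twoPosTable()
    regions <- data.frame(mouse_id = "m1", position_id = c("p1", "p2"),
                          region_label = c("Void", "TAMM/Oligo"))
    ra <- assignRegions(tab, regions)
    expect_equal(ra$region_label[ra$position_id == "p1"],
                 c("Void", "Void"))
    expect_equal(ra$region_label[ra$position_id == "p2"], "TAMM/Oligo")

    # per-cell override wins over the position label
    regions2 <- rbind(cbind(regions, cell_id = NA),
                      data.frame(mouse_id = "m1", position_id = "p1",
                                 region_label = "TAMM/vascularized",
                                 cell_id = "2"))
    ra2 <- assignRegions(tab, regions2)
    expect_equal(ra2$region_label[ra2$position_id == "p1" &
                                  ra2$track_id == "2"],
                 "TAMM/vascularized")
    expect_equal(ra2$region_label[ra2$position_id == "p1" &
                                  ra2$track_id == "1"], "Void")

    # labels outside the declared set are rejected
    expect_error(assignRegions(tab, regions, levels = c("Void")),
                 "declared set")
    # uncovered positions are listed
    expect_error(assignRegions(tab, regions[1, , drop = FALSE]),
                 "without a region")
})

test_that("cluster frequencies sum to 100 per position and z-score per
           mouse", {
    # 10 tracks in one position: 7 in cluster 1, 3 in cluster 2
    ids <- sprintf("%d", 1:10)
    df <- do.call(rbind, lapply(ids, function(i)
        trackDf(t = 0:3, x = 0:3, track_id = i)))
    df2 <- df; df2$position_id <- "p2"
    tab <- TrackTable(rbind(df, df2))
    gid <- trackIds(tab)
    lab <- c(rep(1L, 7), rep(2L, 3), rep(1L, 5), rep(2L, 5))
    names(lab) <- c(paste0("m1.p1.", ids), paste0("m1.p2.", ids))
    res <- new("ClusterResult", trackIndex = names(lab),
               embedding = matrix(0, 20, 2), labels = unname(lab),
               k = 2L, seed = 1L, params = list())
    regions <- data.frame(mouse_id = "m1", position_id = c("p1", "p2"),
                          region_label = c("Void", "Void"))
    ra <- assignRegions(tab, regions)
    fr <- clusterFrequencies(res, ra)
    p1 <- fr[fr$position_id == "p1", ]
    expect_equal(p1$pct[p1$cluster == 1], 70)
    expect_equal(p1$pct[p1$cluster == 2], 30)
    # conservation per position
    expect_equal(as.numeric(tapply(fr$pct,
                                   paste(fr$mouse_id, fr$position_id),
                                   sum)),
                 c(100, 100))
    # z-scores across a mouse's positions: mean 0, sd 1
    for (cl in 1:2) {
        z <- fr$z_pct[fr$cluster == cl]
        expect_equal(mean(z), 0, tolerance = 1e-12)
        expect_equal(sd(z), 1, tolerance = 1e-12)
    }
    # permuting track order leaves the table unchanged
    perm <- sample(length(lab))
    res2 <- new("ClusterResult", trackIndex = names(lab)[perm],
                embedding = matrix(0, 20, 2), labels = unname(lab)[perm],
                k = 2L, seed = 1L, params = list())
    expect_equal(clusterFrequencies(res2, ra), fr)
})

test_that("a single-position mouse yields missing z-scores", {
    df <- rbind(trackDf(t = 0:3, x = 0:3, track_id = "1"),
                trackDf(t = 0:3, x = 4:7, track_id = "2"))
    tab <- TrackTable(df)
    res <- new("ClusterResult", trackIndex = trackIds(tab),
               embedding = matrix(0, 2, 2), labels = c(1L, 2L), k = 2L,
               seed = 1L, params = list())
    ra <- assignRegions(tab, data.frame(mouse_id = "m1",
                                        position_id = "p1",
                                        region_label = "Void"))
    fr <- suppressWarnings(clusterFrequencies(res, ra))
    expect_true(all(is.na(fr$z_pct)))
})

test_that("two-region comparison reduces Tukey to the ANOVA pair", {
    set.seed(61)
    fr <- expand.grid(mouse_id = sprintf("m%d", 1:3),
                      position_id = sprintf("p%d", 1:4), cluster = 1L)
    fr$region_label <- rep(c("Void", "TAMM/Oligo"),
                           length.out = nrow(fr))
    fr$pct <- runif(nrow(fr), 10, 50)
    fr$z_pct <- suppressWarnings(
        zscoreWithin(fr$pct, paste(fr$mouse_id, fr$cluster)))
    out <- compareRegions(fr)
    expect_equal(nrow(out$anova), 1L)
    expect_equal(out$tukey$p_adj, out$anova$p, tolerance = 1e-9)
})

test_that("a planted region enrichment is detected across replicates", {
    rejections <- 0L
    for (rep in 1:20) {
        sc <- sceneConfig(
            archetypePresets("easy", 10L), n_mice = 3L,
            positions_per_mouse = 6L, dropout_rate = 0,
            region_labels = c("Void", "TAMM/Oligo", "TAMM/vascularized"),
            region_enrichment = list("TAMM/vascularized" =
                                         c(invading = 3)),
            seed = 700L + rep)
        sim <- simulateTracks(sc)
        res <- truthClusterResult(sim)
        ra <- assignRegions(sim$table, sim$regions)
        fr <- clusterFrequencies(res, ra)
        out <- suppressWarnings(compareRegions(fr))
        lev <- levels(factor(sim$truth$archetype))
        pInv <- out$anova$p[out$anova$cluster == which(lev == "invading")]
        if (length(pInv) && !is.na(pInv) && pInv < 0.05) {
            rejections <- rejections + 1L
        }
    }
    expect_gte(rejections, 18L)
})

test_that("null region comparisons are calibrated", {
    set.seed(62)
    rej <- 0L; total <- 0L
    for (rep in 1:200) {
        fr <- expand.grid(mouse_id = sprintf("m%d", 1:3),
                          position_id = sprintf("p%d", 1:6), cluster = 1L)
        fr$region_label <- rep(c("Void", "TAMM/Oligo",
                                 "TAMM/vascularized"),
                               length.out = nrow(fr))
        fr$pct <- rnorm(nrow(fr), mean = 20, sd = 5)
        fr$z_pct <- suppressWarnings(
            zscoreWithin(fr$pct, paste(fr$mouse_id, fr$cluster)))
        out <- suppressWarnings(compareRegions(fr, use_z = FALSE))
        if (!is.null(out$anova)) {
            total <- total + 1L
            if (out$anova$p < 0.05) rej <- rej + 1L
        }
    }
    expect_gte(total, 200L)
    expect_gte(rej / total, 0.02)
    expect_lte(rej / total, 0.08)
})
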