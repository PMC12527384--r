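# Large-scale phenotyping: externally defined TME regions (e.g. from a
# spatial phenotyping toolbox run on fixed correlative imaging) are
# consumed as input -- never recomputed -- and behavioral-cluster
# frequencies are compared across them.

#' Assign tracks to TME regions
#'
#' Region discovery happens in an external spatial-phenotyping tool; its
#' export is consumed here. Two granularities are supported: a
#' per-position label (every track in the position inherits it; the
#' default, matching how imaged positions are matched to regions) and a
#' per-cell table (column `cell_id` = track id) whose labels take
#' precedence over position labels.
#'
#' @param table a [TrackTable-class].
#' @param regions data.frame with `mouse_id`, `position_id`,
#'   `region_label`, and optionally `cell_id` for per-cell rows.
#' @param levels declared region label set; labels outside it are an
#'   error. Default: the labels present in `regions`.
#' @return data.frame (mouse_id, position_id, track_id, region_label),
#'   one row per track.
#' @export
assignRegions <- function(table, regions, levels = NULL) {
    stopifnot(is(table, "TrackTable"),
              all(c("mouse_id", "position_id", "region_label") %in%
                  names(regions)))
    if (is.null(levels)) levels <- unique(regions$region_label)
    bad <- setdiff(regions$region_label, levels)
    if (length(bad)) {
        stop("region label(s) not in the declared set: ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    tracks <- unique(trackData(table)[, c("mouse_id", "position_id",
                                          "track_id")])
    hasCell <- "cell_id" %in% names(regions) & if ("cell_id" %in%
        names(regions)) !is.na(regions$cell_id) else FALSE
    posReg <- regions[!hasCell, c("mouse_id", "position_id",
                                  "region_label"), drop = FALSE]
    posReg <- unique(posReg)
    if (anyDuplicated(posReg[, c("mouse_id", "position_id")])) {
        stop("conflicting region labels for a position", call. = FALSE)
    }
    pk <- paste(tracks$mouse_id, tracks$position_id, sep = "\r")
    lab <- posReg$region_label[match(pk, paste(posReg$mouse_id,
                                               posReg$position_id,
                                               sep = "\r"))]
    if (any(hasCell)) {
        cellReg <- regions[hasCell, , drop = FALSE]
        ck <- paste(tracks$mouse_id, tracks$position_id, tracks$track_id,
                    sep = "\r")
        hit <- match(ck, paste(cellReg$mouse_id, cellReg$position_id,
                               cellReg$cell_id, sep = "\r"))
        lab[!is.na(hit)] <- cellReg$region_label[hit[!is.na(hit)]]
    }
    if (anyNA(lab)) {
        un <- unique(pk[is.na(lab)])
        stop("positions/cells without a region label: ",
             paste(head(gsub("\r", "/", un), 5), collapse = ", "),
             call. = FALSE)
    }
    cbind(tracks, region_label = lab, stringsAsFactors = FALSE)
}

#' Per-position behavioral-cluster frequencies, z-scored per mouse
#'
#' For every imaged position the percentage of its tracks falling in
#' each behavioral cluster is computed (all clusters, including absent
#' ones at 0%, so the percentages sum to 100 per position). To account
#' for inter-mouse variability the percentages are then z-scored within
#' each (mouse, cluster) group across that mouse's positions; a mouse
#' with a single position has no within-mouse spread and its z-scores
#' are NA.
#'
#' @param result a [ClusterResult-class].
#' @param regionAssign data.frame from [assignRegions()].
#' @return data.frame with one row per (mouse, position, cluster):
#'   `pct`, `z_pct`, `region_label`.
#' @export
clusterFrequencies <- function(result, regionAssign) {
    stopifnot(is(result, "ClusterResult"))
    lab <- clusterLabels(result)
    gid <- paste(regionAssign$mouse_id, regionAssign$position_id,
                 regionAssign$track_id, sep = ".")
    miss <- setdiff(gid, names(lab))
    if (length(miss)) {
        stop("tracks without a cluster label: ",
             paste(head(miss, 5), collapse = ", "), call. = FALSE)
    }
    ra <- regionAssign
    ra$cluster <- as.integer(lab[gid])
    pos <- unique(ra[, c("mouse_id", "position_id", "region_label")])
    grid <- merge(pos, data.frame(cluster = seq_len(result@k)))
    cnt <- aggregate(list(n = ra$cluster),
                     by = list(mouse_id = ra$mouse_id,
                               position_id = ra$position_id,
                               cluster = ra$cluster), FUN = length)
    out <- merge(grid, cnt,
                 by = c("mouse_id", "position_id", "cluster"),
                 all.x = TRUE)
    out$n[is.na(out$n)] <- 0L
    tot <- stats::ave(out$n, paste(out$mouse_id, out$position_id),
                      FUN = sum)
    out$pct <- 100 * out$n / tot
    out$z_pct <- suppressWarnings(
        zscoreWithin(out$pct, paste(out$mouse_id, out$cluster)))
    out <- out[order(out$mouse_id, out$position_id, out$cluster), ]
    rownames(out) <- NULL
    out
}

#' Compare cluster frequencies across TME regions
#'
#' For each behavioral cluster: one-way ANOVA of the z-scored
#' percentages across regions, followed by Tukey HSD pairwise
#' comparisons. Clusters whose groups are degenerate (fewer than 2
#' regions with data, or no variance) are skipped with a warning.
#'
#' @param freqs table from [clusterFrequencies()].
#' @param use_z use the per-mouse z-scored percentages (default) or the
#'   raw percentages.
#' @return list with `anova` (data.frame: cluster, F, df1, df2, p) and
#'   `tukey` (data.frame of pairwise region contrasts per cluster).
#' @export
compareRegions <- function(freqs, use_z = TRUE) {
    val <- if (use_z) freqs$z_pct else freqs$pct
    res <- list(); tuk <- list()
    for (cl in sort(unique(freqs$cluster))) {
        idx <- freqs$cluster == cl & !is.na(val)
        v <- val[idx]; g <- freqs$region_label[idx]
        tab <- table(g)
        if (length(tab) < 2L || all(tab < 2L)) {
            warning("cluster ", cl, ": degenerate region groups; skipped",
                    call. = FALSE)
            next
        }
        a <- tryCatch(oneWayAnova(v, g), error = function(e) NULL)
        if (is.null(a)) next
        res[[as.character(cl)]] <- data.frame(
            cluster = cl, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
        tk <- tryCatch(tukeyHsd(v, g), error = function(e) NULL)
        if (!is.null(tk)) {
            tk$cluster <- cl
            tuk[[as.character(cl)]] <- tk
        }
    }
    list(anova = do.call(rbind, c(res, make.row.names = FALSE)),
         tukey = do.call(rbind, c(tuk, make.row.names = FALSE)))
}
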