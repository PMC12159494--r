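# Trajectory pattern taxonomy. Event delay maps are (a) clustered
# descriptively (binarised occupancy -> SVD scores -> k-means into spatial
# clusters, then k = 2 directional subclusters on delay-slope vectors) and
# (b) assigned one of the six named travelling patterns (or
# UNCLASSIFIED_STATIC) by an explicit rule on atlas occupancy and delay
# gradients, so that labels are reproducible rather than read off by eye.

#' Delay-map feature matrices for clustering
#'
#' Per event (with union-footprint area above `minAreaPx`): the flattened
#' binary occupancy of its delay map, and a two-component direction vector
#' (least-squares slope of the delay against column and against row over
#' the footprint, s/px; positive = later toward higher column/row index).
#'
#' @param eventSet an [EventSet-class] with features.
#' @param minAreaPx exclude events with footprint area <= this (default 5).
#' @return list with `binary` (`n x P` matrix), `direction` (`n x 2`),
#'   `eventIds` and `gridDim`.
#' @export
buildDelayFeatures <- function(eventSet, minAreaPx = 5) {
    d <- eventSet@dims
    P <- d[1] * d[2]
    keep <- which(vapply(eventSet@events,
                         function(e) length(e$unionIdx) > minAreaPx, TRUE))
    if (!length(keep)) stop("no events with footprint area > ", minAreaPx)
    B <- matrix(0, length(keep), P)
    D <- matrix(0, length(keep), 2,
                dimnames = list(NULL, c("horizontal", "vertical")))
    for (j in seq_along(keep)) {
        e <- eventSet@events[[keep[j]]]
        if (is.null(e$delayMap)) stop("run eventFeatures() first")
        B[j, e$delayMap$idx] <- 1
        rr <- (e$delayMap$idx - 1L) %% d[1] + 1L
        cc <- (e$delayMap$idx - 1L) %/% d[1] + 1L
        D[j, 1] <- .lsSlope(cc, e$delayMap$delaySec)
        D[j, 2] <- .lsSlope(rr, e$delayMap$delaySec)
    }
    list(binary = B, direction = D,
         eventIds = vapply(eventSet@events[keep], function(e) e$id, 1L),
         gridDim = d[1:2])
}

.lsSlope <- function(x, y) {
    vx <- sum((x - mean(x))^2)
    if (vx == 0) return(0)
    sum((x - mean(x)) * (y - mean(y))) / vx
}

#' Cluster events by delay-map location and propagation direction
#'
#' Binary occupancy maps are reduced by SVD to at most `svdComponents`
#' scores (capped at the matrix rank) and k-means clustered into
#' `kSpatial` spatial clusters; within each spatial cluster a k = 2 k-means
#' on the direction vectors yields the directional subclusters.
#' Deterministic for a given `seed`.
#'
#' @param features list from [buildDelayFeatures()].
#' @param kSpatial number of spatial clusters (default 4).
#' @param svdComponents SVD score cap (default 3000; at desk scale the rank
#'   is far smaller).
#' @param restarts k-means restarts (default 10).
#' @param seed RNG seed (default 1).
#' @return list with `spatial` and `directional` integer assignments and
#'   `eventIds`.
#' @export
clusterPatterns <- function(features, kSpatial = 4L, svdComponents = 3000L,
                            restarts = 10L, seed = 1L) {
    B <- features$binary
    n <- nrow(B)
    if (n < kSpatial)
        stop("need at least ", kSpatial, " events to form ", kSpatial,
             " clusters (have ", n, ")")
    set.seed(as.integer(seed))
    nc <- min(as.integer(svdComponents), n, ncol(B))
    sv <- svd(B, nu = nc, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(nc)], nc)
    km <- kmeans(scores, centers = kSpatial, nstart = restarts,
                 iter.max = 100L)
    spatial <- km$cluster
    directional <- integer(n)
    for (cl in seq_len(kSpatial)) {
        ii <- which(spatial == cl)
        if (length(ii) < 2L) { directional[ii] <- 1L; next }
        dv <- features$direction[ii, , drop = FALSE]
        if (nrow(unique(dv)) < 2L) { directional[ii] <- 1L; next }
        directional[ii] <- kmeans(dv, centers = 2L, nstart = restarts,
                                  iter.max = 100L)$cluster
    }
    list(spatial = spatial, directional = directional,
         eventIds = features$eventIds)
}

#' Assign trajectory pattern labels to events
#'
#' Rule-based labelling from the event's centroid trajectory (its delay
#' ordering in space) on the atlas territories: non-dynamic events are
#' `UNCLASSIFIED_STATIC`; trajectories running between cortex and
#' hippocampus are `CORTICO_HIPPOCAMPAL`/`HIPPOCAMPO_CORTICAL` by
#' direction; cortex to/from other subcortex is `CORTICO_SUBCORTICAL`
#' (a single direction-agnostic class, matching the taxonomy); cortical
#' trajectories crossing the midline are `TRANSHEMISPHERIC`; remaining
#' cortical trajectories are `MEDIO_TEMPORAL` or `TEMPORO_MEDIAL` by
#' whether the distance from the midline grows or shrinks. Trajectories
#' failing the rule margins stay `UNCLASSIFIED_STATIC`.
#'
#' @param eventSet a classified [EventSet-class] with features.
#' @param atlas the [RoiAtlas-class].
#' @param marginPx minimum net displacement (pixels) for a directional
#'   call (default 3).
#' @return the [EventSet-class] with per-event `pattern` labels set.
#' @export
labelPatterns <- function(eventSet, atlas, marginPx = 3) {
    if (!length(atlas@hemispheres))
        stop("atlas lacks hemisphere information")
    cls <- regionClassMap(atlas)
    d <- eventSet@dims
    if (!identical(dim(cls), d[1:2]))
        stop("atlas grid does not match the event grid")
    mid <- (d[2] + 1) / 2
    for (i in seq_along(eventSet@events)) {
        e <- eventSet@events[[i]]
        if (is.null(e$dynamic))
            stop("run classifyDynamic() before labelPatterns()")
        eventSet@events[[i]]$pattern <- .labelOne(e, cls, mid, marginPx)
    }
    eventSet
}

.labelOne <- function(e, cls, mid, marginPx) {
    if (!isTRUE(e$dynamic)) return("UNCLASSIFIED_STATIC")
    tr <- e$centroidTrack
    n <- nrow(tr)
    if (n < 2L) return("UNCLASSIFIED_STATIC")
    rr <- pmin(pmax(round(tr[, 2]), 1L), nrow(cls))
    cc <- pmin(pmax(round(tr[, 3]), 1L), ncol(cls))
    k <- cls[cbind(rr, cc)]
    # the raised-cosine envelope hides the trajectory's first and last
    # stretch below threshold; extrapolate a few pixels beyond each end so
    # the origin/destination territory still gets counted
    lookup <- function(p) {
        p <- round(p)
        if (p[1] < 1 || p[1] > nrow(cls) || p[2] < 1 || p[2] > ncol(cls))
            return(0L)
        cls[p[1], p[2]]
    }
    Lt <- sum(sqrt(rowSums((tr[-1L, 2:3, drop = FALSE] -
                            tr[-n, 2:3, drop = FALSE])^2)))
    steps <- pmin(pmax(c(0.12, 0.25, 0.4) * Lt, c(2, 4, 6)), 18)
    extend <- function(pt, dir) {
        nd <- sqrt(sum(dir^2))
        if (nd == 0) return(integer())
        dir <- dir / nd
        vapply(steps, function(s) lookup(pt + s * dir), 0L)
    }
    m <- min(3L, n)
    kPre <- extend(tr[1, 2:3], tr[1, 2:3] - tr[m, 2:3])
    kPost <- extend(tr[n, 2:3], tr[n, 2:3] - tr[n - m + 1L, 2:3])
    k <- c(rev(kPre), k, kPost)
    n2 <- length(k)
    thr <- max(2L, ceiling(0.08 * n2))      # minimum dwell to count a territory
    iCtx <- which(k == 1L); iHip <- which(k == 2L); iSub <- which(k == 3L)
    if (length(iCtx) >= thr && length(iHip) >= thr)
        return(if (mean(iCtx) < mean(iHip)) "CORTICO_HIPPOCAMPAL"
               else "HIPPOCAMPO_CORTICAL")
    if (length(iCtx) >= thr && length(iSub) >= thr)
        return("CORTICO_SUBCORTICAL")
    if (length(iCtx) >= 0.6 * n2) {
        sideStart <- sign(cc[1] - mid); sideEnd <- sign(cc[n] - mid)
        if (sideStart != 0 && sideEnd != 0 && sideStart != sideEnd &&
            abs(cc[n] - cc[1]) > marginPx)
            return("TRANSHEMISPHERIC")
        dmid <- abs(cc[n] - mid) - abs(cc[1] - mid)
        if (abs(dmid) <= marginPx) return("UNCLASSIFIED_STATIC")
        return(if (dmid > 0) "MEDIO_TEMPORAL" else "TEMPORO_MEDIAL")
    }
    "UNCLASSIFIED_STATIC"
}

#' Per-scan pattern proportion tables
#'
#' Percentages of each pattern label per scan (summing to 100), plus a
#' second table renormalised over the six travelling classes only
#' (excluding `UNCLASSIFIED_STATIC`).
#'
#' @param labels data.frame with columns `scan` and `pattern` (one row per
#'   event); scans with no events may be listed via the `scans` argument.
#' @param scans optional character vector of all scan names (to include
#'   empty scans as flagged rows).
#' @return list with `all` and `travellingOnly` data.frames
#'   (`scan`, `pattern`, `pct`) plus `empty` (scans without events).
#' @export
patternFrequencies <- function(labels, scans = NULL) {
    lv <- patternLabels()
    scans <- scans %||% unique(labels$scan)
    empty <- setdiff(scans, unique(labels$scan))
    tabs <- list(); tabsT <- list()
    for (s in intersect(scans, unique(labels$scan))) {
        pat <- labels$pattern[labels$scan == s]
        tt <- table(factor(pat, levels = lv))
        tabs[[s]] <- data.frame(scan = s, pattern = lv,
                                pct = 100 * as.numeric(tt) / sum(tt),
                                row.names = NULL)
        trav <- pat[pat != "UNCLASSIFIED_STATIC"]
        lvT <- setdiff(lv, "UNCLASSIFIED_STATIC")
        if (length(trav)) {
            ttT <- table(factor(trav, levels = lvT))
            tabsT[[s]] <- data.frame(scan = s, pattern = lvT,
                                     pct = 100 * as.numeric(ttT) / sum(ttT),
                                     row.names = NULL)
        }
    }
    list(all = if (length(tabs)) do.call(rbind, tabs) else NULL,
         travellingOnly = if (length(tabsT)) do.call(rbind, tabsT) else NULL,
         empty = empty)
}
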