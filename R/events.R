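# Spatiotemporal CBV-increase event detection on wave-band filtered movies.
# Pipeline: per-pixel robust z-scoring (noise sd from the median absolute
# temporal first difference, rescaled by the band's first-difference gain)
# -> spatial Gaussian smoothing -> supra-threshold mask -> spatiotemporal
# connected components (8-neighbour within a frame, frame-adjacent
# components linked by >= 1 px footprint overlap) -> size filtering.

#' Detector configuration
#'
#' @param zThreshold significance threshold in robust z units (default 5).
#' @param minSizePx minimum single-frame footprint in pixels (default 15).
#' @param smoothingSigmaPx spatial Gaussian smoothing sd in pixels
#'   (default 0.5).
#' @param dynamicThresholdPx propagation distance above which an event is
#'   dynamic/travelling (default 5).
#' @param band wave band in Hz the movie is filtered to (default
#'   0.08-0.15).
#' @param minPeakAmplitudePct optional minimum peak relative-CBV gate in
#'   percent (0 = disabled; the z criterion is the operative test).
#' @param minNoiseSd lower bound on the estimated noise sd (intensity
#'   units). Keeps the z-score finite and meaningful on degenerate
#'   (noise-free synthetic) input, where the estimated sd would otherwise
#'   collapse to the machine floor and zero-phase filter ringing would
#'   become "significant". 0 (default) disables the bound.
#' @return a validated configuration list.
#' @export
detectorConfig <- function(zThreshold = 5, minSizePx = 15,
                           smoothingSigmaPx = 0.5, dynamicThresholdPx = 5,
                           band = c(0.08, 0.15), minPeakAmplitudePct = 0,
                           minNoiseSd = 0, noiseQuantile = 0.25) {
    stopifnot(zThreshold > 0, minSizePx > 0, smoothingSigmaPx > 0,
              dynamicThresholdPx > 0, minPeakAmplitudePct >= 0,
              minNoiseSd >= 0, noiseQuantile > 0, noiseQuantile <= 0.5)
    list(zThreshold = zThreshold, minSizePx = as.integer(minSizePx),
         smoothingSigmaPx = smoothingSigmaPx,
         dynamicThresholdPx = dynamicThresholdPx, band = band,
         minPeakAmplitudePct = minPeakAmplitudePct, minNoiseSd = minNoiseSd,
         noiseQuantile = noiseQuantile)
}

# rms gain of the first-difference operator over a frequency band:
# g^2 = mean over the band of (2 sin(pi f dt))^2. Over the full (0, Nyquist]
# range this equals 2, recovering the white-noise sqrt(2) factor.
.diffGain <- function(band, dt) {
    lo <- band[1]; hi <- band[2]
    g2 <- (2 * (hi - lo) - (sin(2 * pi * hi * dt) - sin(2 * pi * lo * dt)) /
               (pi * dt)) / (hi - lo)
    sqrt(g2)
}

#' Robust per-pixel z-scoring of a band-filtered movie
#'
#' Normalises each pixel's filtered series by a noise sd estimated from a
#' low quantile of its absolute temporal first differences:
#' `sd = Q_q(|diff|) / (Phi^-1((1+q)/2) * g)`, where `g` is the rms
#' first-difference gain of the noise band. With `quantile = 0.5` this is
#' the classic MAD-of-differences estimate (`median|diff| * 1.4826 /
#' sqrt(2)` for broadband input); the default `quantile = 0.25` stays
#' robust when high-amplitude oscillatory epochs occupy up to ~75% of the
#' record, as they do in an oscillation-rich (inflamed) brain state. For
#' broadband (white) input `g = sqrt(2)`; for a narrow band such as
#' 0.08-0.15 Hz at dt = 0.4 s, `g` is ~0.30, keeping z standard-normal for
#' band-limited noise.
#'
#' @param movie a [FusMovie-class], already filtered to `band`.
#' @param band the noise band in Hz, or `NULL` for broadband input.
#' @param minNoiseSd lower bound on the estimated sd (see
#'   [detectorConfig()]).
#' @param quantile quantile of `|diff|` used for estimation (default 0.25).
#' @return list with `z` (array), `noiseSd` (matrix) and `gain`.
#' @export
robustZScore <- function(movie, band = NULL, minNoiseSd = 0,
                         quantile = 0.25) {
    spec <- movie@spec
    dt <- spec@dt
    g <- if (is.null(band)) sqrt(2) else .diffGain(band, dt)
    X <- movie@data
    dim(X) <- c(spec@height * spec@width, spec@nFrames)
    sdv <- cpp_diff_quantile(t(X), quantile) /
        (stats::qnorm((1 + quantile) / 2) * g)
    floorv <- .Machine$double.eps * max(max(abs(X)), 1)
    nz <- sdv < floorv
    if (any(nz) && minNoiseSd <= floorv)
        warning(sum(nz), " zero-variance pixels: noise sd floored")
    sdv <- pmax(sdv, floorv, minNoiseSd)
    Z <- X / sdv
    dim(Z) <- c(spec@height, spec@width, spec@nFrames)
    list(z = Z, noiseSd = matrix(sdv, spec@height, spec@width), gain = g)
}

.gaussKernel1d <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
}

#' Smooth every frame of a z-movie with a spatial Gaussian
#'
#' @param z 3-D array.
#' @param sigmaPx Gaussian sd in pixels.
#' @return smoothed array of the same shape.
#' @export
smoothFrames <- function(z, sigmaPx) {
    d <- dim(z)
    k <- .gaussKernel1d(sigmaPx)
    out <- cpp_smooth_frames(as.numeric(z), d[1], d[2], d[3], k)
    dim(out) <- d
    out
}

#' Detect spatiotemporal CBV-increase events
#'
#' Smooths the z-movie spatially, thresholds at `zThreshold`, and groups
#' supra-threshold voxels into spatiotemporal connected components
#' (8-neighbourhood within frames; consecutive frames connected wherever
#' footprints share a pixel). Components whose largest single-frame
#' footprint is below `minSizePx` are discarded. An empty result is valid.
#'
#' @param z z-array from [robustZScore()] (or its result list).
#' @param config [detectorConfig()].
#' @param spec the movie's [AcquisitionSpec-class].
#' @return An [EventSet-class] with footprints, frame ranges, seeds and
#'   peak z (features are added by [eventFeatures()]).
#' @export
detectEvents <- function(z, config = detectorConfig(), spec) {
    if (is.list(z)) z <- z$z
    if (!all(is.finite(z))) stop("z-movie must be finite")
    d <- dim(z)
    zs <- smoothFrames(z, config$smoothingSigmaPx)
    idx <- which(zs > config$zThreshold)
    ev <- list()
    if (length(idx)) {
        h <- d[1]; w <- d[2]; T <- d[3]
        id <- array(0L, d)
        id[idx] <- seq_along(idx)
        rct <- arrayInd(idx, d)
        offs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                     c(1L, -1L, 0L), c(0L, 0L, 1L))
        el <- vector("list", length(offs))
        for (i in seq_along(offs)) {
            o <- offs[[i]]
            r2 <- rct[, 1] + o[1]; c2 <- rct[, 2] + o[2]; t2 <- rct[, 3] + o[3]
            ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w & t2 <= T
            nb <- id[cbind(r2[ok], c2[ok], t2[ok])]
            has <- nb > 0L
            el[[i]] <- cbind(which(ok)[has], nb[has])
        }
        el <- do.call(rbind, el)
        memb <- if (is.null(el) || !nrow(el)) seq_along(idx) else {
            gr <- igraph::make_graph(t(el), n = length(idx), directed = FALSE)
            igraph::components(gr)$membership
        }
        comps <- split(seq_along(idx), memb)
        eid <- 0L
        for (cp in comps) {
            tvec <- rct[cp, 3]
            fpSizes <- tabulate(tvec - min(tvec) + 1L)
            if (max(fpSizes) < config$minSizePx) next
            eid <- eid + 1L
            pix <- (rct[cp, 2] - 1L) * h + rct[cp, 1]    # within-frame linear index
            byFrame <- split(pix, tvec)
            zvals <- zs[idx[cp]]
            imax <- which.max(zvals)
            ev[[eid]] <- list(
                id = eid,
                tStart = min(tvec), tEnd = max(tvec),
                frames = as.integer(names(byFrame)),
                footprints = byFrame,
                unionIdx = sort(unique(pix)),
                seed = c(rct[cp, 1][imax], rct[cp, 2][imax], tvec[imax]),
                peakZ = zvals[imax])
        }
    }
    new("EventSet", events = ev, dims = as.integer(d), dt = spec@dt,
        pixelMm = spec@pixelMm, config = config)
}

#' Compute per-event features
#'
#' Fills each event with its z-weighted per-frame centroid track, the
#' propagation distance (sum of consecutive centroid displacements, px and
#' mm), peak relative-CBV amplitude within the footprint, duration, delay
#' map (per-pixel peak-z time minus event onset, seconds) and mean centroid
#' speed (`propagation_mm / elapsed_s`; 0 with a `degenerate` flag for
#' single-frame events).
#'
#' @param eventSet an [EventSet-class] from [detectEvents()].
#' @param pctMovie ΔCBV% array (from [percentChange()] of the raw movie).
#' @param z the (smoothed or raw) z-array used for weighting; the smoothed
#'   array used for detection is the stable choice.
#' @return the completed [EventSet-class].
#' @export
eventFeatures <- function(eventSet, pctMovie, z) {
    d <- eventSet@dims
    h <- d[1]
    dt <- eventSet@dt
    pxmm <- eventSet@pixelMm
    # centroid weights are the above-threshold excess (z - z_thr)+, so the
    # track does not wobble with the threshold contour itself
    zoff <- eventSet@config$zThreshold %||% 0
    for (i in seq_along(eventSet@events)) {
        e <- eventSet@events[[i]]
        nFr <- length(e$frames)
        track <- matrix(NA_real_, nFr, 3,
                        dimnames = list(NULL, c("frame", "row", "col")))
        for (j in seq_len(nFr)) {
            t <- e$frames[j]
            pix <- e$footprints[[j]]
            rr <- (pix - 1L) %% h + 1L
            cc <- (pix - 1L) %/% h + 1L
            wz <- z[cbind(rr, cc, t)] - zoff
            wz <- pmax(wz, 0); sw <- sum(wz)
            if (sw <= 0) wz <- rep(1, length(pix)) / length(pix) else wz <- wz / sw
            track[j, ] <- c(t, sum(wz * rr), sum(wz * cc))
        }
        if (nFr >= 3L) {
            # 3-frame running mean: suppresses per-frame centroid estimation
            # jitter (which would otherwise accumulate linearly into the
            # propagation sum) without biasing uniform motion
            sm <- track[, 2:3]
            sm[2:(nFr - 1L), ] <- (track[1:(nFr - 2L), 2:3] +
                                   track[2:(nFr - 1L), 2:3] +
                                   track[3:nFr, 2:3]) / 3
            track[, 2:3] <- sm
        }
        prop <- if (nFr > 1)
            sum(sqrt(rowSums((track[-1, 2:3, drop = FALSE] -
                              track[-nFr, 2:3, drop = FALSE])^2))) else 0
        # delay map: per union pixel, time of max z within the event window
        rr <- (e$unionIdx - 1L) %% h + 1L
        cc <- (e$unionIdx - 1L) %/% h + 1L
        win <- e$tStart:e$tEnd
        zwin <- z[cbind(rep(rr, each = length(win)),
                        rep(cc, each = length(win)),
                        rep.int(win, length(rr)))]
        dim(zwin) <- c(length(win), length(rr))
        delay <- (win[apply(zwin, 2, which.max)] - e$tStart) * dt
        pixPeakZ <- apply(zwin, 2, max)
        degenerate <- nFr == 1L
        elapsed <- (e$tEnd - e$tStart) * dt
        if (!is.null(pctMovie)) {
            amp <- max(pctMovie[cbind(rep(rr, each = length(win)),
                                      rep(cc, each = length(win)),
                                      rep.int(win, length(rr)))])
        } else amp <- NA_real_
        e$centroidTrack <- track
        e$propagationPx <- prop
        e$propagationMm <- prop * pxmm
        e$peakAmplitudePct <- amp
        e$durationS <- (e$tEnd - e$tStart + 1) * dt
        e$delayMap <- list(idx = e$unionIdx, delaySec = delay,
                           peakZ = pixPeakZ)
        e$speedMmS <- if (degenerate || elapsed <= 0) 0 else prop * pxmm / elapsed
        e$degenerate <- degenerate
        eventSet@events[[i]] <- e
    }
    eventSet
}

#' Classify events as dynamic (travelling) or static
#'
#' An event is dynamic when its propagation distance exceeds
#' `dynamicThresholdPx` (default 5 px).
#'
#' @param eventSet an [EventSet-class] with features.
#' @param dynamicThresholdPx override of the configured threshold.
#' @return the [EventSet-class] with `dynamic` flags set.
#' @export
classifyDynamic <- function(eventSet, dynamicThresholdPx = NULL) {
    thr <- dynamicThresholdPx %||% eventSet@config$dynamicThresholdPx %||% 5
    for (i in seq_along(eventSet@events)) {
        e <- eventSet@events[[i]]
        if (is.null(e$propagationPx))
            stop("run eventFeatures() before classifyDynamic()")
        eventSet@events[[i]]$dynamic <- e$propagationPx > thr
    }
    eventSet
}

#' Per-scan event summary
#'
#' Percentage of dynamic events and feature means over the dynamic events
#' only (as used for group comparisons). With no events the counts are 0
#' and the means are `NA` with `undefinedMeans = TRUE`.
#'
#' @param eventSet a classified [EventSet-class].
#' @return one-row data.frame with `nEvents`, `nDynamic`, `pctDynamic`,
#'   `meanAmplitudePct`, `meanPropagationMm`, `meanSpeedMmS`,
#'   `undefinedMeans`.
#' @export
scanEventSummary <- function(eventSet) {
    df <- as.data.frame(eventSet)
    n <- nrow(df)
    nd <- sum(df$dynamic %in% TRUE)
    dyn <- df[df$dynamic %in% TRUE, , drop = FALSE]
    data.frame(
        nEvents = n, nDynamic = nd,
        pctDynamic = if (n > 0) 100 * nd / n else NA_real_,
        meanAmplitudePct = if (nd > 0) mean(dyn$peakAmplitudePct) else NA_real_,
        meanPropagationMm = if (nd > 0) mean(dyn$propagationMm) else NA_real_,
        meanSpeedMmS = if (nd > 0) mean(dyn$speedMmS) else NA_real_,
        undefinedMeans = nd == 0)
}

#' End-to-end event analysis of a raw movie
#'
#' Band-pass to the wave band, robust z-scoring, detection, feature
#' extraction (ΔCBV% against the whole-series mean) and dynamic/static
#' classification.
#'
#' @param movie a raw [FusMovie-class].
#' @param config [detectorConfig()].
#' @return a classified [EventSet-class].
#' @export
analyzeEvents <- function(movie, config = detectorConfig()) {
    filt <- bandpassMovie(movie, config$band)
    rz <- robustZScore(filt, band = config$band,
                       minNoiseSd = config$minNoiseSd %||% 0,
                       quantile = config$noiseQuantile %||% 0.25)
    zs <- smoothFrames(rz$z, config$smoothingSigmaPx)
    es <- detectEvents(rz$z, config, movie@spec)
    pct <- percentChange(movie, "mean")
    es <- eventFeatures(es, pct@data, zs)
    if (config$minPeakAmplitudePct > 0) {
        keep <- vapply(es@events, function(e)
            e$peakAmplitudePct >= config$minPeakAmplitudePct, TRUE)
        es@events <- es@events[keep]
    }
    classifyDynamic(es)
}

#' Propagation speed of a wave from its sequence of detected events
#'
#' A multi-cycle wave is detected as one event per carrier cycle. Within
#' one event the centroid's apparent motion is biased for slow waves (the
#' band filter's temporal smearing advances the above-threshold blob), but
#' the displacement of the mean event position between successive cycles
#' is not: the bias pattern repeats each cycle and cancels. This estimator
#' therefore regresses the per-event mean centroid on the per-event mean
#' time when two or more events are available, and falls back to the
#' single event's centroid speed otherwise.
#'
#' @param eventSet an [EventSet-class] with features.
#' @param eventIds ids of the events belonging to one wave (e.g. all
#'   events matched to one ground-truth entry by [matchEventsToTruth()]).
#' @return speed in mm/s.
#' @export
waveSpeedFromEvents <- function(eventSet, eventIds) {
    evs <- Filter(function(e) e$id %in% eventIds, eventSet@events)
    if (!length(evs)) stop("no events with the given ids")
    if (length(evs) == 1L) return(evs[[1]]$speedMmS)
    tm <- vapply(evs, function(e) mean(e$centroidTrack[, 1]), 1) *
        eventSet@dt
    pr <- vapply(evs, function(e) mean(e$centroidTrack[, 2]), 1)
    pc <- vapply(evs, function(e) mean(e$centroidTrack[, 3]), 1)
    vt <- sum((tm - mean(tm))^2)
    if (vt == 0) return(evs[[1]]$speedMmS)
    vr <- sum((tm - mean(tm)) * (pr - mean(pr))) / vt
    vc <- sum((tm - mean(tm)) * (pc - mean(pc))) / vt
    sqrt(vr^2 + vc^2) * eventSet@pixelMm
}

#' Match detected events to the simulator's ground truth
#'
#' A ground-truth event is recovered when at least one detected event
#' overlaps it in time with a centroid within `tolPx` pixels; each detected
#' event is assigned the closest overlapping ground-truth entry.
#'
#' @param eventSet a classified [EventSet-class] with features.
#' @param groundTruth a [GroundTruthLog-class].
#' @param tolPx spatial matching tolerance in pixels (default 10).
#' @return list with `truth` (data.frame: ground-truth id, detected flag,
#'   number of matching events) and `events` (data.frame: event id, matched
#'   ground-truth id or NA, truth dynamic flag).
#' @export
matchEventsToTruth <- function(eventSet, groundTruth, tolPx = 10) {
    gts <- groundTruth@events
    evs <- eventSet@events
    gtHit <- integer(length(gts))
    gtBest <- rep(NA_integer_, length(gts))
    gtBestD <- rep(Inf, length(gts))
    evGt <- rep(NA_integer_, length(evs))
    evDist <- rep(Inf, length(evs))
    h <- eventSet@dims[1]
    for (gi in seq_along(gts)) {
        g <- gts[[gi]]
        if (!nrow(g$centroidTrack)) next
        gfr <- g$centroidTrack[, 1]
        for (ei in seq_along(evs)) {
            e <- evs[[ei]]
            common <- intersect(gfr, e$centroidTrack[, 1])
            if (!length(common)) next
            gi2 <- match(common, gfr)
            ei2 <- match(common, e$centroidTrack[, 1])
            dAll <- sqrt((g$centroidTrack[gi2, 2] - e$centroidTrack[ei2, 2])^2 +
                         (g$centroidTrack[gi2, 3] - e$centroidTrack[ei2, 3])^2)
            dmin <- min(dAll)
            dmean <- mean(dAll)
            hit <- dmin <= tolPx
            if (!hit) {
                # a wave can be subsumed in a larger merged event whose
                # centroid sits elsewhere: fall back to footprint proximity
                # at a few overlapping frames
                probe <- common[unique(round(seq(1, length(common),
                                                 length.out = 3)))]
                for (fr in probe) {
                    pix <- e$footprints[[match(fr, e$frames)]]
                    if (is.null(pix)) next
                    pr <- (pix - 1L) %% h + 1L
                    pc <- (pix - 1L) %/% h + 1L
                    gp <- g$centroidTrack[match(fr, gfr), 2:3]
                    if (min(sqrt((pr - gp[1])^2 + (pc - gp[2])^2)) <= tolPx / 2) {
                        hit <- TRUE; break
                    }
                }
            }
            if (hit) {
                gtHit[gi] <- gtHit[gi] + 1L
                # event-to-truth assignment: mean track distance, so a
                # large merged event is attributed to the trajectory it
                # follows, not to a small event it brushes past
                if (dmin <= tolPx && dmean < evDist[ei]) {
                    evDist[ei] <- dmean; evGt[ei] <- gi
                }
                # the truth's primary event: longest shared support, then
                # closest mean distance
                score <- dmean - length(common)
                if (score < gtBestD[gi]) {
                    gtBestD[gi] <- score; gtBest[gi] <- ei
                }
            }
        }
    }
    list(truth = data.frame(
             gtId = vapply(gts, function(g) g$id, 1L),
             detected = gtHit > 0L, nMatches = gtHit,
             primaryEvent = gtBest,
             primaryDynamic = vapply(seq_along(gts), function(i)
                 if (is.na(gtBest[i])) NA
                 else isTRUE(evs[[gtBest[i]]]$dynamic), TRUE)),
         events = data.frame(
             eventId = vapply(evs, function(e) e$id, 1L),
             gtId = evGt,
             truthDynamic = vapply(seq_along(evs), function(i)
                 if (is.na(evGt[i])) NA else gts[[evGt[i]]]$dynamic, TRUE)))
}
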