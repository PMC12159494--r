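# Ground-truthed synthetic vasomotion movies. Baseline Power Doppler is a
# per-region constant plus per-pixel white and 1/f temporal noise; events
# (travelling waves, static CBV increases, stimulation responses) compose
# multiplicatively on the movie, since Power Doppler is proportional to CBV
# and relative change is the analysed quantity. Wave carriers are
# raised-cosine (nonnegative) so injected events are CBV increases.

#' Default baseline Power Doppler intensity per region (arbitrary units)
#'
#' Cortical regions are slightly brighter than deep territories, mimicking
#' depth attenuation; background tissue sits at 60.
#' @return named numeric vector (regions plus `"background"`).
#' @export
baselineDefaults <- function() {
    c(PrimVisCtx = 120, SecVisCtx = 115, RetroDysCtx = 110,
      RetroGrCtx_A = 105, RetroGrCtx_B = 100, SuperiorColl = 95,
      Hippocampus = 100, DorsalMidbrain = 90, VentralMidbrain = 85,
      background = 60)
}

#' Default temporal noise parameters
#'
#' White plus `1/f` noise on baselines of order 100 a.u.; the in-band
#' (0.08-0.15 Hz) noise sd is then about 1.1% of baseline, so that
#' raised-cosine waves of 10-30% peak amplitude span detector z-scores
#' of roughly 4-13, straddling the z > 5 detection threshold.
#' @return list with `whiteSd`, `pinkSd`, `pinkExponent`.
#' @export
noiseDefaults <- function() list(whiteSd = 4.6, pinkSd = 1.0, pinkExponent = 1.0)

#' Per-pixel baseline image implied by an atlas
#'
#' @param atlas a [RoiAtlas-class].
#' @param baselines named numeric vector as [baselineDefaults()].
#' @return numeric matrix of baseline intensities.
#' @export
baselineImage <- function(atlas, baselines = baselineDefaults()) {
    lab <- atlas@labels
    img <- matrix(baselines[["background"]], nrow(lab), ncol(lab))
    for (id in roiIds(atlas)) {
        nm <- atlas@regionNames[[as.character(id)]]
        img[lab == id] <- baselines[[nm]]
    }
    img
}

#' Analytic noise sd within a frequency band
#'
#' Standard deviation of the white + `1/f` noise model restricted to a band,
#' computed on the discrete Fourier grid actually used by the generator.
#'
#' @param noise list as [noiseDefaults()].
#' @param nFrames,dt record length and frame period.
#' @param band numeric `c(low, high)` in Hz, or `NULL` for the full spectrum.
#' @return noise sd in intensity units.
#' @export
bandNoiseSd <- function(noise, nFrames, dt, band = NULL) {
    T <- nFrames
    k <- seq_len(T - 1L)
    f <- pmin(k, T - k) / (T * dt)
    inband <- if (is.null(band)) rep(TRUE, length(f)) else f >= band[1] & f <= band[2]
    vw <- noise$whiteSd^2 * sum(inband) / T
    w2 <- f^(-noise$pinkExponent)
    w2 <- w2 / mean(c(0, w2))                  # mean over all T bins (DC = 0) is 1
    vp <- noise$pinkSd^2 * sum(w2[inband]) / T
    sqrt(vw + vp)
}

#' Simulate a resting baseline movie (no events)
#'
#' Per-region constant baseline plus independent per-pixel temporal noise:
#' a white component and a `1/f^exponent` component synthesised by spectral
#' shaping of white noise. Identical seed and configuration give a
#' bit-identical movie.
#'
#' @param atlas a [RoiAtlas-class].
#' @param spec an [AcquisitionSpec-class] matching the atlas grid.
#' @param noise list as [noiseDefaults()] (sds in intensity units, >= 0).
#' @param seed integer seed (required, for reproducibility).
#' @param baselines named numeric vector as [baselineDefaults()].
#' @return A [FusMovie-class].
#' @export
simulateBaseline <- function(atlas, spec, noise = noiseDefaults(), seed,
                             baselines = baselineDefaults()) {
    stopifnot(!missing(seed))
    if (!all(is.finite(c(noise$whiteSd, noise$pinkSd, noise$pinkExponent))))
        stop("noise parameters must be finite")
    if (noise$whiteSd < 0 || noise$pinkSd < 0)
        stop("noise sds must be >= 0")
    h <- spec@height; w <- spec@width; T <- spec@nFrames
    if (!identical(dim(atlas@labels), c(h, w)))
        stop("atlas grid does not match acquisition spec")
    set.seed(as.integer(seed))
    base <- baselineImage(atlas, baselines)
    data <- array(rep(base, T), dim = c(h, w, T))
    P <- h * w
    if (noise$whiteSd > 0 || noise$pinkSd > 0) {
        dim(data) <- c(P, T)
        # pink spectral weights on the two-sided grid, DC removed
        k <- seq_len(T) - 1L
        f <- pmin(k, T - k) / (T * spec@dt)
        wgt <- c(0, f[-1]^(-noise$pinkExponent / 2))
        wgt <- wgt / sqrt(mean(wgt^2))
        chunk <- 4096L
        for (s in seq.int(1L, P, by = chunk)) {
            e <- min(P, s + chunk - 1L)
            n <- e - s + 1L
            if (noise$whiteSd > 0)
                data[s:e, ] <- data[s:e, ] +
                    noise$whiteSd * matrix(rnorm(n * T), n, T)
            if (noise$pinkSd > 0) {
                # shape iid complex Gaussians in the frequency domain; the
                # real and imaginary parts of the inverse transform are two
                # independent unit-variance 1/f series per column
                nc2 <- ceiling(n / 2)
                F <- matrix(complex(real = rnorm(T * nc2),
                                    imaginary = rnorm(T * nc2)), T, nc2) * wgt
                pk <- mvfft(F, inverse = TRUE) / sqrt(T)
                both <- cbind(Re(pk), Im(pk))[, seq_len(n), drop = FALSE]
                data[s:e, ] <- data[s:e, ] + noise$pinkSd * t(both)
            }
        }
        dim(data) <- c(h, w, T)
    }
    data[data <= 0] <- 1e-3                    # Power Doppler intensity is positive
    fusMovie(data, spec)
}

# --- path helpers ---------------------------------------------------------

.pathCum <- function(path) {
    if (nrow(path) < 2L) return(0)
    d <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
    c(0, cumsum(d))
}

.posAlong <- function(path, cum, dist) {
    L <- cum[length(cum)]
    dist <- pmin(pmax(dist, 0), L)
    if (L == 0) return(matrix(rep(path[1L, ], length(dist)),
                              ncol = 2L, byrow = TRUE))
    seg <- findInterval(dist, cum, rightmost.closed = TRUE)
    seg <- pmin(seg, nrow(path) - 1L)
    frac <- (dist - cum[seg]) / pmax(cum[seg + 1L] - cum[seg], 1e-12)
    path[seg, , drop = FALSE] +
        (path[seg + 1L, , drop = FALSE] - path[seg, , drop = FALSE]) * frac
}

# multiply movie by (1 + amp_t * bump_t) for one event's frame sequence;
# bumps are truncated at 3 sigma so the modulation is exactly local.
# `data` must be a private copy: it is modified in place (C++ core).
.injectBumps <- function(data, rows, cols, amps, frames, sigmaPx) {
    d <- dim(data)
    cpp_inject_bumps(data, d[1], d[2], as.numeric(rows), as.numeric(cols),
                     as.numeric(amps), as.integer(frames), sigmaPx)
    data
}

.appendGt <- function(gt, entry) {
    entry$id <- length(gt@events) + 1L
    gt@events[[length(gt@events) + 1L]] <- entry
    gt
}

#' Inject a travelling haemodynamic wave into a movie
#'
#' Multiplies the movie by `1 + m(x, t)` where `m` is a Gaussian spatial
#' bump (sd `widthMm`, truncated at 3 sd) whose centre advances along the
#' wave's path at its speed, carrying a raised-cosine oscillation at its
#' frequency with peak relative amplitude `amplitudePct`/100. The true
#' centroid track, path length and dynamic flag are appended to the
#' ground-truth log.
#'
#' @param movie a [FusMovie-class].
#' @param atlas the [RoiAtlas-class] (geometry checks).
#' @param wave a [WaveSpec-class].
#' @param groundTruth a [GroundTruthLog-class].
#' @param peakZ optional expected detector peak z-score recorded as ground
#'   truth (computed by the cohort generators via [bandNoiseSd()]).
#' @param dynamicThresholdPx path-length threshold used for the true
#'   dynamic flag (default 5, the travelling-wave criterion).
#' @return list with elements `movie` and `groundTruth`.
# kinematics of one wave on the acquisition grid: active frames, centre
# positions, raised-cosine amplitudes, true track and path length
.waveKinematics <- function(wave, spec) {
    h <- spec@height; w <- spec@width
    if (any(wave@path[, 1] < 1 | wave@path[, 1] > h |
            wave@path[, 2] < 1 | wave@path[, 2] > w))
        stop("wave path waypoints must lie inside the image")
    nAct <- max(2L, round(wave@nCycles / wave@freqHz / spec@dt))
    t0 <- as.integer(wave@tOnset)
    t1 <- t0 + nAct - 1L
    if (t0 < 1L || t1 > spec@nFrames)
        stop("wave active window [", t0, ", ", t1, "] does not fit in the movie")
    tt <- t0:t1
    pxPerFrame <- wave@speedMmS * spec@dt / spec@pixelMm
    cum <- .pathCum(wave@path)
    pos <- .posAlong(wave@path, cum, (tt - t0) * pxPerFrame)
    phase <- 2 * pi * wave@freqHz * (tt - t0) * spec@dt
    amp <- (wave@amplitudePct / 100) / 2 * (1 - cos(phase))
    pathLen <- sum(sqrt(rowSums((pos[-1L, , drop = FALSE] -
                                 pos[-nrow(pos), , drop = FALSE])^2)))
    list(tt = tt, pos = pos, amp = amp, t0 = t0, t1 = t1,
         sigmaPx = wave@widthMm / spec@pixelMm, pathLen = pathLen,
         track = cbind(frame = tt, row = pos[, 1], col = pos[, 2]))
}

.gtWaveEntry <- function(wave, k, peakZ, dynamicThresholdPx) {
    list(kind = "wave", pattern = wave@pattern, tStart = k$t0, tEnd = k$t1,
         centroidTrack = k$track, pathLengthPx = k$pathLen,
         dynamic = k$pathLen > dynamicThresholdPx,
         amplitudePct = wave@amplitudePct, freqHz = wave@freqHz,
         speedMmS = wave@speedMmS, widthMm = wave@widthMm, peakZ = peakZ)
}

#' @export
injectTravellingWave <- function(movie, atlas, wave, groundTruth,
                                 peakZ = NA_real_, dynamicThresholdPx = 5) {
    validObject(wave)
    spec <- movie@spec
    k <- .waveKinematics(wave, spec)
    data <- movie@data + 0          # private copy, modified in place below
    data <- .injectBumps(data, k$pos[, 1], k$pos[, 2], k$amp, k$tt, k$sigmaPx)
    gt <- .appendGt(groundTruth, .gtWaveEntry(wave, k, peakZ,
                                              dynamicThresholdPx))
    list(movie = fusMovie(data, spec), groundTruth = gt)
}

#' Inject a static (non-travelling) CBV increase
#'
#' Same multiplicative bump model as [injectTravellingWave()] but with a
#' fixed centre and a single raised-cosine temporal cycle spanning
#' `durationFrames`, so the pixel returns to baseline after the event.
#' The true path length is 0 and the dynamic flag is `FALSE`.
#'
#' @param movie a [FusMovie-class].
#' @param atlas the [RoiAtlas-class].
#' @param centre numeric `(row, col)`.
#' @param amplitudePct peak relative amplitude, percent (> 0).
#' @param durationFrames event duration in frames (>= 2).
#' @param widthMm Gaussian footprint sd in mm.
#' @param tOnset first active frame.
#' @param groundTruth a [GroundTruthLog-class].
#' @param peakZ optional expected detector peak z-score (ground truth).
#' @return list with elements `movie` and `groundTruth`.
#' @export
injectStaticEvent <- function(movie, atlas, centre, amplitudePct,
                              durationFrames, widthMm, tOnset, groundTruth,
                              peakZ = NA_real_) {
    spec <- movie@spec
    if (amplitudePct <= 0 || widthMm <= 0)
        stop("amplitudePct and widthMm must be positive")
    if (centre[1] < 1 || centre[1] > spec@height ||
        centre[2] < 1 || centre[2] > spec@width)
        stop("event centre must lie inside the image")
    t0 <- as.integer(tOnset)
    nAct <- as.integer(durationFrames)
    if (nAct < 2L) stop("durationFrames must be >= 2")
    t1 <- t0 + nAct - 1L
    if (t0 < 1L || t1 > spec@nFrames)
        stop("event window does not fit in the movie")
    sigmaPx <- widthMm / spec@pixelMm
    data <- movie@data + 0          # private copy, modified in place below
    tt <- t0:t1
    amp <- (amplitudePct / 100) / 2 * (1 - cos(2 * pi * (tt - t0) / nAct))
    data <- .injectBumps(data, rep(centre[1], nAct), rep(centre[2], nAct),
                         amp, tt, sigmaPx)
    track <- cbind(frame = tt, row = rep(centre[1], nAct),
                   col = rep(centre[2], nAct))
    gt <- .appendGt(groundTruth, list(
        kind = "static", pattern = "UNCLASSIFIED_STATIC", tStart = t0,
        tEnd = t1, centroidTrack = track, pathLengthPx = 0, dynamic = FALSE,
        amplitudePct = amplitudePct, freqHz = NA_real_, speedMmS = NA_real_,
        widthMm = widthMm, peakZ = peakZ))
    list(movie = fusMovie(data, spec), groundTruth = gt)
}

# --- trajectory templates on the schematic atlas --------------------------

#' Canonical names of the travelling-wave trajectory classes
#'
#' Six travelling patterns plus the static/unclassified class.
#' @return character vector of the seven labels.
#' @export
patternLabels <- function() {
    c("MEDIO_TEMPORAL", "TEMPORO_MEDIAL", "TRANSHEMISPHERIC",
      "CORTICO_SUBCORTICAL", "CORTICO_HIPPOCAMPAL", "HIPPOCAMPO_CORTICAL",
      "UNCLASSIFIED_STATIC")
}

#' Waypoints of a canonical trajectory for one pattern class
#'
#' Builds a `(row, col)` waypoint path on the schematic atlas realising one
#' of the six travelling patterns: cortical medial-to-temporal (and
#' reverse), trans-hemispheric cortical, cortex to hippocampus (and
#' reverse), and cortex to non-hippocampal subcortex.
#'
#' @param atlas a [RoiAtlas-class].
#' @param pattern one of the six travelling [patternLabels()].
#' @param hemisphere `"left"` or `"right"` (ignored for TRANSHEMISPHERIC).
#' @param jitterPx uniform waypoint jitter (pixels), drawn from the current
#'   RNG stream; 0 for the deterministic template.
#' @return numeric matrix of waypoints.
#' @export
patternPath <- function(atlas, pattern, hemisphere = "left", jitterPx = 0) {
    lab <- atlas@labels
    w <- ncol(lab)
    ctr <- function(name, hemi) roiCentroid(atlas, lookupRoi(atlas, name, hemi)[1])
    p <- switch(pattern,
        MEDIO_TEMPORAL = rbind(ctr("RetroGrCtx_A", hemisphere),
                               ctr("PrimVisCtx", hemisphere)),
        TEMPORO_MEDIAL = rbind(ctr("PrimVisCtx", hemisphere),
                               ctr("RetroGrCtx_A", hemisphere)),
        TRANSHEMISPHERIC = rbind(ctr("SecVisCtx", "left"),
                                 ctr("RetroGrCtx_B", "left"),
                                 ctr("RetroGrCtx_B", "right"),
                                 ctr("SecVisCtx", "right")),
        CORTICO_HIPPOCAMPAL = rbind(ctr("SecVisCtx", hemisphere),
                                    ctr("Hippocampus", hemisphere)),
        HIPPOCAMPO_CORTICAL = rbind(ctr("Hippocampus", hemisphere),
                                    ctr("SecVisCtx", hemisphere)),
        CORTICO_SUBCORTICAL = rbind(ctr("RetroGrCtx_B", hemisphere),
                                    ctr("SuperiorColl", hemisphere),
                                    ctr("DorsalMidbrain", hemisphere)),
        stop("no trajectory template for pattern '", pattern, "'"))
    if (jitterPx > 0)
        p <- p + matrix(runif(length(p), -jitterPx, jitterPx), nrow(p), 2L)
    p[, 1] <- pmin(pmax(p[, 1], 2), nrow(lab) - 1)
    p[, 2] <- pmin(pmax(p[, 2], 2), w - 1)
    p
}

# direction-reversed pattern name (the trajectory classes come in
# direction pairs; TRANSHEMISPHERIC and CORTICO_SUBCORTICAL are their own
# reverses in the taxonomy)
.reversePattern <- function(pattern) {
    switch(pattern,
        MEDIO_TEMPORAL = "TEMPORO_MEDIAL",
        TEMPORO_MEDIAL = "MEDIO_TEMPORAL",
        CORTICO_HIPPOCAMPAL = "HIPPOCAMPO_CORTICAL",
        HIPPOCAMPO_CORTICAL = "CORTICO_HIPPOCAMPAL",
        pattern)
}

# --- cohort generation ----------------------------------------------------

#' Default per-arm configuration for cohort simulation
#'
#' `"VEH-like"`: sparse, low-amplitude cortical medio-temporal and
#' temporo-medial waves plus occasional static events.
#' `"LPS-like"`: sustained quasi-periodic reciprocating oscillatory trains
#' in the cortical ribbon (high amplitude, ~0.1 Hz bouts with inter-bout
#' gaps) plus frequent discrete waves drawn from all six patterns and
#' static events.
#'
#' @param arm `"VEH-like"` or `"LPS-like"`.
#' @return configuration list understood by [simulateCohort()].
#' @export
cohortArmConfig <- function(arm) {
    switch(arm,
        "VEH-like" = list(
            arm = arm,
            trains = NULL,
            waves = list(ratePerMin = 0.5,
                         patterns = c("MEDIO_TEMPORAL", "TEMPORO_MEDIAL"),
                         amplitudeRange = c(10, 22), speedRange = c(0.2, 0.5),
                         freqRange = c(0.08, 0.15), widthMm = 0.8,
                         nCycles = 1),
            statics = list(ratePerMin = 0.7, amplitudeRange = c(10, 22),
                           durationS = c(6, 12), widthMm = 0.7)),
        "LPS-like" = list(
            arm = arm,
            trains = list(amplitudePct = 60, freqRange = c(0.09, 0.13),
                          nCyclesRange = c(2L, 3L), widthMm = 1.2,
                          gapS = c(70, 100),
                          patterns = c("MEDIO_TEMPORAL", "CORTICO_HIPPOCAMPAL")),
            waves = list(ratePerMin = 1.2,
                         patterns = c("MEDIO_TEMPORAL", "TEMPORO_MEDIAL",
                                      "TRANSHEMISPHERIC", "CORTICO_SUBCORTICAL",
                                      "CORTICO_HIPPOCAMPAL", "HIPPOCAMPO_CORTICAL"),
                         patternWeights = c(0.30, 0.26, 0.12, 0.10, 0.10, 0.12),
                         amplitudeRange = c(22, 38), speedRange = c(0.2, 0.6),
                         freqRange = c(0.08, 0.15), widthMm = 0.8,
                         nCycles = 1),
            statics = list(ratePerMin = 1.5, amplitudeRange = c(15, 30),
                           durationS = c(6, 12), widthMm = 0.7)),
        stop("unknown arm '", arm, "': use 'VEH-like' or 'LPS-like'"))
}

# draw one discrete wave spec for the cohort (NULL if it does not fit)
.drawCohortWave <- function(atlas, cfgw, t0, spec, base, sdBand) {
    pat <- if (!is.null(cfgw$patternWeights))
        sample(cfgw$patterns, 1L, prob = cfgw$patternWeights)
    else sample(cfgw$patterns, 1L)
    hemi <- sample(c("left", "right"), 1L)
    path <- patternPath(atlas, pat, hemi, jitterPx = 5)
    amp <- runif(1, cfgw$amplitudeRange[1], cfgw$amplitudeRange[2])
    fr <- runif(1, cfgw$freqRange[1], cfgw$freqRange[2])
    cum <- .pathCum(path)
    L <- cum[length(cum)] * spec@pixelMm
    # speed so the path is covered within the active cycles, clipped to range
    sp <- min(max(L * fr / cfgw$nCycles, cfgw$speedRange[1]), cfgw$speedRange[2])
    nAct <- round(cfgw$nCycles / fr / spec@dt)
    if (t0 + nAct > spec@nFrames) return(NULL)
    wv <- waveSpec(path, speedMmS = sp, freqHz = fr, amplitudePct = amp,
                   widthMm = cfgw$widthMm, tOnset = t0, nCycles = cfgw$nCycles,
                   pattern = pat)
    mid <- .posAlong(path, cum, cum[length(cum)] / 2)
    pz <- (amp / 100) / 2 * base[round(mid[1]), round(mid[2])] *
        .bandGain(fr, c(0.08, 0.15), spec@dt) / sdBand
    list(wave = wv, peakZ = pz)
}

# The detector's difference-quantile noise estimate is inflated wherever
# scheduled events occupy part of the record: with signal-bearing frame
# fraction fs at a pixel, the q-quantile estimate stretches by
# qnorm((1 + q/(1-fs))/2) / qnorm((1+q)/2). The simulator knows its own
# schedule, so the logged ground-truth peak z is divided by this factor at
# each event's reference pixel (ring margin of ~8 frames per event side).
.dutyAdjustPeakZ <- function(gt, spec, sdBand, base, q = 0.25,
                             ringFrames = 8L) {
    evs <- gt@events
    n <- length(evs)
    if (n < 2L || !is.finite(sdBand)) return(gt)
    T <- spec@nFrames
    for (i in seq_len(n)) {
        ei <- evs[[i]]
        if (!nrow(ei$centroidTrack)) next
        p <- ei$centroidTrack[ceiling(nrow(ei$centroidTrack) / 2), 2:3]
        busy <- rep(FALSE, T)
        for (j in seq_len(n)) {
            ej <- evs[[j]]
            trk <- ej$centroidTrack
            if (!nrow(trk)) next
            d <- sqrt((trk[, 2] - p[1])^2 + (trk[, 3] - p[2])^2)
            sigPx <- ej$widthMm / spec@pixelMm
            if (!is.finite(sigPx)) next
            aAbs <- (ej$amplitudePct / 100) / 2 *
                base[round(p[1]), round(p[2])] * exp(-d^2 / (2 * sigPx^2))
            hot <- trk[aAbs >= sdBand, 1]
            if (length(hot)) {
                a <- max(1L, min(hot) - ringFrames)
                b <- min(T, max(hot) + ringFrames)
                busy[a:b] <- TRUE
            }
        }
        fs <- min(mean(busy), 1 - q / 0.999)
        infl <- stats::qnorm((1 + min(q / (1 - fs), 0.999)) / 2) /
            stats::qnorm((1 + q) / 2)
        evs[[i]]$peakZ <- ei$peakZ / infl
    }
    gt@events <- evs
    gt
}

#' Simulate one ground-truthed scan of a cohort arm
#'
#' @param atlas a [RoiAtlas-class].
#' @param spec an [AcquisitionSpec-class].
#' @param config arm configuration from [cohortArmConfig()].
#' @param noise noise parameters, see [noiseDefaults()].
#' @param seed integer seed.
#' @return list with `movie` and `groundTruth`.
#' @export
simulateScan <- function(atlas, spec, config, noise = noiseDefaults(), seed) {
    movie <- simulateBaseline(atlas, spec, noise, seed = seed)
    data <- movie@data + 0          # single private copy, events applied in place
    gt <- emptyGroundTruth()
    durMin <- spec@nFrames * spec@dt / 60
    base <- baselineImage(atlas)
    sdBand <- bandNoiseSd(noise, spec@nFrames, spec@dt, c(0.08, 0.15))
    if (sdBand == 0) sdBand <- NA_real_
    addWave <- function(wv, pz) {
        k <- .waveKinematics(wv, spec)
        data <<- .injectBumps(data, k$pos[, 1], k$pos[, 2], k$amp, k$tt,
                              k$sigmaPx)
        gt <<- .appendGt(gt, .gtWaveEntry(wv, k, pz, 5))
    }

    # quasi-periodic oscillatory wave trains (LPS-like arms): repeated
    # multi-cycle sweeps along a fixed trajectory, alternating direction
    # between bouts, separated by rest gaps
    if (!is.null(config$trains)) {
        tr <- config$trains
        for (pat in tr$patterns) {
            for (hemi in c("left", "right")) {
                t0 <- 1L + round(runif(1, 0, 25))
                forward <- TRUE
                while (TRUE) {
                    fr <- runif(1, tr$freqRange[1], tr$freqRange[2])
                    tpl <- patternPath(atlas, pat, hemi, jitterPx = 3)
                    if (!forward) tpl <- tpl[rev(seq_len(nrow(tpl))), , drop = FALSE]
                    cum <- .pathCum(tpl)
                    # cycles chosen so each carrier cycle travels ~20 px,
                    # well clear of the 5 px travelling-wave criterion
                    nc <- max(tr$nCyclesRange[1],
                              min(tr$nCyclesRange[2],
                                  round(cum[length(cum)] / 20)))
                    nAct <- round(nc / fr / spec@dt)
                    if (t0 + nAct - 1L > spec@nFrames) break
                    Lmm <- cum[length(cum)] * spec@pixelMm
                    sp <- min(max(Lmm * fr / nc, 0.1), 0.8)
                    wv <- waveSpec(tpl, speedMmS = sp, freqHz = fr,
                                   amplitudePct = tr$amplitudePct,
                                   widthMm = tr$widthMm, tOnset = t0,
                                   nCycles = nc,
                                   pattern = if (forward) pat
                                             else .reversePattern(pat))
                    pz <- (tr$amplitudePct / 100) / 2 *
                        base[round(tpl[1, 1]), round(tpl[1, 2])] *
                        .bandGain(fr, c(0.08, 0.15), spec@dt) / sdBand
                    addWave(wv, pz)
                    forward <- !forward
                    gap <- round(runif(1, tr$gapS[1], tr$gapS[2]) / spec@dt)
                    t0 <- t0 + nAct + gap
                }
            }
        }
    }

    # discrete waves (Poisson-scheduled)
    if (!is.null(config$waves) && config$waves$ratePerMin > 0) {
        nW <- rpois(1L, config$waves$ratePerMin * durMin)
        if (nW > 0) {
            onsets <- sort(round(runif(nW, 1, spec@nFrames - 60)))
            for (t0 in onsets) {
                dw <- .drawCohortWave(atlas, config$waves, t0, spec, base, sdBand)
                if (!is.null(dw)) addWave(dw$wave, dw$peakZ)
            }
        }
    }

    # static localized CBV increases
    if (!is.null(config$statics) && config$statics$ratePerMin > 0) {
        cs <- config$statics
        nS <- rpois(1L, cs$ratePerMin * durMin)
        lab <- atlas@labels
        inside <- which(lab > 0, arr.ind = TRUE)
        for (i in seq_len(nS)) {
            ctr <- as.numeric(inside[sample.int(nrow(inside), 1L), ])
            amp <- runif(1, cs$amplitudeRange[1], cs$amplitudeRange[2])
            durF <- round(runif(1, cs$durationS[1], cs$durationS[2]) / spec@dt)
            t0 <- sample.int(spec@nFrames - durF - 1L, 1L)
            ttS <- t0:(t0 + durF - 1L)
            ampS <- (amp / 100) / 2 * (1 - cos(2 * pi * (ttS - t0) / durF))
            data <- .injectBumps(data, rep(ctr[1], durF), rep(ctr[2], durF),
                                 ampS, ttS, cs$widthMm / spec@pixelMm)
            gt <- .appendGt(gt, list(
                kind = "static", pattern = "UNCLASSIFIED_STATIC", tStart = t0,
                tEnd = t0 + durF - 1L,
                centroidTrack = cbind(frame = ttS, row = rep(ctr[1], durF),
                                      col = rep(ctr[2], durF)),
                pathLengthPx = 0, dynamic = FALSE, amplitudePct = amp,
                freqHz = NA_real_, speedMmS = NA_real_, widthMm = cs$widthMm,
                peakZ = (amp / 100) / 2 * base[ctr[1], ctr[2]] *
                    .bandGain(1 / (durF * spec@dt), c(0.08, 0.15), spec@dt) /
                    sdBand))
        }
    }
    gt <- .dutyAdjustPeakZ(gt, spec, sdBand, base)
    list(movie = fusMovie(data, spec), groundTruth = gt)
}

#' Simulate a cohort of ground-truthed scans
#'
#' Generates `nScans` scans per listed arm with per-scan seeds derived from
#' `seed`, so that timings differ between scans while the arm-level
#' statistics are shared.
#'
#' @param nScans scans per arm (>= 1).
#' @param arms character vector of arm names (see [cohortArmConfig()]).
#' @param spec an [AcquisitionSpec-class].
#' @param noise noise parameters.
#' @param seed integer master seed.
#' @param atlas optional [RoiAtlas-class]; built from `spec` if missing.
#' @return list of per-scan lists `(movie, groundTruth, arm, seed)`.
#' @export
simulateCohort <- function(nScans, arms = c("VEH-like", "LPS-like"), spec,
                           noise = noiseDefaults(), seed, atlas = NULL) {
    if (nScans < 1L) stop("nScans must be >= 1")
    if (is.null(atlas)) atlas <- buildAtlas(spec)
    out <- list()
    i <- 0L
    for (arm in arms) {
        cfg <- cohortArmConfig(arm)
        for (s in seq_len(nScans)) {
            i <- i + 1L
            scanSeed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
            st <- simulateScan(atlas, spec, cfg, noise, seed = scanSeed)
            out[[i]] <- list(movie = st$movie, groundTruth = st$groundTruth,
                             arm = arm, seed = scanSeed)
        }
    }
    out
}

#' Simulate a noise-free (or low-noise) cohort containing all six patterns
#'
#' Schedules `nPerPattern` temporally separated single-cycle waves of each
#' travelling pattern in one long scan, for trajectory-label recovery
#' tests. With `noise = NULL` the movie is exactly baseline outside events.
#'
#' @param spec an [AcquisitionSpec-class] (frames are extended if the
#'   schedule does not fit).
#' @param nPerPattern waves per pattern class.
#' @param amplitudePct peak amplitude of every wave.
#' @param noise noise parameters or `NULL` for noiseless.
#' @param seed integer seed.
#' @return list with `movie`, `groundTruth`, `atlas`.
#' @export
simulateSixPatternCohort <- function(spec, nPerPattern = 10,
                                     amplitudePct = 25, noise = NULL,
                                     seed = 1) {
    pats <- setdiff(patternLabels(), "UNCLASSIFIED_STATIC")
    nW <- nPerPattern * length(pats)
    slotFrames <- 40L                       # 1 cycle at 0.1 Hz (25 fr) + gap
    need <- nW * slotFrames + 20L
    if (spec@nFrames < need)
        spec <- acquisitionSpec(spec@height, spec@width, need,
                                dt = spec@dt, pixelMm = spec@pixelMm)
    atlas <- buildAtlas(spec)
    nz <- if (is.null(noise)) list(whiteSd = 0, pinkSd = 0, pinkExponent = 1)
          else noise
    movie <- simulateBaseline(atlas, spec, nz, seed = seed)
    st <- list(movie = movie, groundTruth = emptyGroundTruth())
    sched <- sample(rep(pats, nPerPattern))
    base <- baselineImage(atlas)
    sdBand <- if (is.null(noise)) NA_real_
              else bandNoiseSd(noise, spec@nFrames, spec@dt, c(0.08, 0.15))
    t0 <- 5L
    for (pat in sched) {
        hemi <- sample(c("left", "right"), 1L)
        path <- patternPath(atlas, pat, hemi, jitterPx = 2)
        fr <- runif(1, 0.09, 0.13)
        cum <- .pathCum(path)
        L <- cum[length(cum)] * spec@pixelMm
        sp <- L * fr                        # cover the path in one cycle
        nAct <- round(1 / fr / spec@dt)
        wv <- waveSpec(path, speedMmS = sp, freqHz = fr,
                       amplitudePct = amplitudePct, widthMm = 0.8,
                       tOnset = t0, nCycles = 1, pattern = pat)
        mid <- .posAlong(path, cum, cum[length(cum)] / 2)
        pz <- if (is.na(sdBand)) Inf else
            (amplitudePct / 100) / 2 * base[round(mid[1]), round(mid[2])] *
                .bandGain(fr, c(0.08, 0.15), spec@dt) / sdBand
        st <- injectTravellingWave(st$movie, atlas, wv, st$groundTruth,
                                   peakZ = pz)
        t0 <- t0 + slotFrames
    }
    list(movie = st$movie, groundTruth = st$groundTruth, atlas = atlas)
}

#' Simulate a visual-stimulation session
#'
#' Baseline movie plus a plateau response in the listed regions during each
#' stimulation block: the block boxcar is convolved with exponential rise
#' and fall kernels and applied multiplicatively with peak relative
#' amplitude `amplitudePct`/100. Optionally superimposes resting-state-like
#' waves (oscillations persisting during stimulation).
#'
#' @param atlas a [RoiAtlas-class].
#' @param spec an [AcquisitionSpec-class]; must cover the protocol.
#' @param protocol a [StimulusProtocol-class].
#' @param response list with `regions` (names), `amplitudePct`, `riseS`,
#'   `fallS`.
#' @param noise noise parameters (use zero sds for a clean session).
#' @param seed integer seed.
#' @param waveConfig optional discrete-wave config as in
#'   [cohortArmConfig()]`$waves`.
#' @return list with `movie`, `groundTruth`, `stim` (logical per frame).
#' @export
simulateStimSession <- function(atlas, spec, protocol = stimulusProtocol(),
                                response = list(regions = c("PrimVisCtx",
                                                            "SecVisCtx"),
                                                amplitudePct = 10,
                                                riseS = 2, fallS = 2),
                                noise = noiseDefaults(), seed = 1,
                                waveConfig = NULL) {
    totS <- protocolDuration(protocol)
    if (totS > spec@nFrames * spec@dt)
        stop("protocol duration (", totS, " s) exceeds the movie duration")
    ids <- unlist(lapply(response$regions, function(nm) lookupRoi(atlas, nm)))
    movie <- simulateBaseline(atlas, spec, noise, seed = seed)
    tsec <- (seq_len(spec@nFrames) - 1L) * spec@dt
    stim <- rep(FALSE, spec@nFrames)
    for (b in seq_len(protocol@nBlocks)) {
        on <- protocol@initialRestS +
            (b - 1L) * (protocol@stimDurS + protocol@restBetweenS)
        stim <- stim | (tsec >= on & tsec < on + protocol@stimDurS)
    }
    # exponential rise during stimulation, exponential return after
    resp <- numeric(spec@nFrames)
    level <- 0
    for (i in seq_len(spec@nFrames)) {
        target <- as.numeric(stim[i])
        tau <- if (stim[i]) max(response$riseS, 1e-6) else max(response$fallS, 1e-6)
        level <- level + (target - level) * (1 - exp(-spec@dt / tau))
        resp[i] <- level
    }
    gain <- 1 + (response$amplitudePct / 100) * resp
    mask <- atlas@labels %in% ids
    data <- movie@data
    dim(data) <- c(spec@height * spec@width, spec@nFrames)
    data[mask, ] <- data[mask, ] * rep(gain, each = sum(mask))
    dim(data) <- c(spec@height, spec@width, spec@nFrames)
    st <- list(movie = fusMovie(data, spec), groundTruth = emptyGroundTruth())
    st$groundTruth <- .appendGt(st$groundTruth, list(
        kind = "stim", pattern = "UNCLASSIFIED_STATIC",
        tStart = which(stim)[1], tEnd = max(which(stim)),
        centroidTrack = matrix(numeric(), 0, 3), pathLengthPx = 0,
        dynamic = FALSE, amplitudePct = response$amplitudePct,
        freqHz = NA_real_, speedMmS = NA_real_, widthMm = NA_real_,
        peakZ = NA_real_))
    if (!is.null(waveConfig)) {
        durMin <- spec@nFrames * spec@dt / 60
        baseImg <- baselineImage(atlas)
        sdBand <- bandNoiseSd(noise, spec@nFrames, spec@dt, c(0.08, 0.15))
        if (sdBand == 0) sdBand <- NA_real_
        nW <- rpois(1L, waveConfig$ratePerMin * durMin)
        onsets <- if (nW > 0) sort(round(runif(nW, 1, spec@nFrames - 60))) else integer()
        for (t0 in onsets) {
            dw <- .drawCohortWave(atlas, waveConfig, t0, spec, baseImg, sdBand)
            if (!is.null(dw))
                st <- injectTravellingWave(st$movie, atlas, dw$wave,
                                           st$groundTruth, peakZ = dw$peakZ)
        }
    }
    list(movie = st$movie, groundTruth = st$groundTruth, stim = stim)
}
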