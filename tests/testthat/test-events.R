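# Event detector: robust z-scoring calibration, connected-component
# detection against the brute-force flood-fill oracle, feature arithmetic
# (propagation, delay maps, speed), and dynamic/static classification.

test_that("robust z is calibrated on white and band-limited noise", {
    set.seed(14)
    spec <- acquisitionSpec(8, 8, 3000)
    raw <- fusMovie(array(100 + 5 * rnorm(8 * 8 * 3000), c(8, 8, 3000)))
    rz <- robustZScore(raw)                   # broadband: sqrt(2) scaling
    zsd <- apply(rz$z, c(1, 2), sd)
    expect_lt(max(abs(zsd - 1)), 0.1)         # standard normal within 10%
    # a slow high-amplitude wave barely inflates the difference-based sd
    t <- (0:2999) * 0.4
    withWave <- movieData(raw)
    withWave[3, 3, ] <- withWave[3, 3, ] + 20 * pmax(sin(2 * pi * 0.1 * t), 0)
    rz2 <- robustZScore(fusMovie(withWave))
    expect_lt(rz2$noiseSd[3, 3] / rz$noiseSd[3, 3], 1.1)
    # scale invariance of z
    rz3 <- robustZScore(fusMovie(movieData(raw) * 2))
    expect_equal(rz3$z, rz$z, tolerance = 1e-12)
    # band-limited noise: band-aware scaling keeps z standard
    bnd <- bandpassMovie(raw, c(0.08, 0.15))
    rzb <- robustZScore(bnd, band = c(0.08, 0.15))
    zsdb <- apply(rzb$z[, , 100:2900], c(1, 2), sd)
    expect_lt(abs(mean(zsdb) - 1), 0.05)
    expect_lt(max(abs(zsdb - 1)), 0.25)
    # with q = 0.5 the estimator reduces to the MAD-of-differences formula
    X <- movieData(raw); dim(X) <- c(64, 3000)
    madEst <- apply(X, 1, function(v) median(abs(diff(v)))) * 1.4826 / sqrt(2)
    rz5 <- robustZScore(raw, quantile = 0.5)
    expect_equal(as.numeric(rz5$noiseSd), madEst, tolerance = 1e-5)
    # zero-variance pixels are floored with a warning
    expect_warning(robustZScore(fusMovie(array(3, c(4, 4, 100)))),
                   "floored")
})

test_that("detected components equal the flood-fill oracle exactly", {
    set.seed(5)
    for (rep in 1:3) {
        z <- array(rnorm(32 * 32 * 100), c(32, 32, 100))
        # implant a few coherent blobs so components of all shapes appear
        for (b in 1:4) {
            r0 <- sample(5:25, 1); c0 <- sample(5:25, 1); t0 <- sample(5:80, 1)
            z[r0:(r0 + 5), c0:(c0 + 5), t0:(t0 + 8)] <- 8 + rnorm(36 * 9)
        }
        cfg <- detectorConfig(zThreshold = 5, minSizePx = 1,
                              smoothingSigmaPx = 0.3)
        zs <- smoothFrames(z, 0.3)
        es <- detectEvents(z, cfg, acquisitionSpec(32, 32, 100))
        oracle <- floodFillOracle(zs > 5)
        expect_identical(eventVoxelSets(es), oracle)
    }
})

test_that("event detection recovers injected waves and rejects pure noise", {
    fx <- oneWaveMovie(speed = 0.4, amp = 30)
    es <- analyzeEvents(fx$movie)
    expect_identical(length(es), 1L)
    mt <- matchEventsToTruth(es, fx$gt)
    expect_true(all(mt$truth$detected))
    # recovered speed within 20% of the injected 0.4 mm/s
    df <- as.data.frame(es)
    expect_lt(abs(df$speedMmS - 0.4) / 0.4, 0.2)
    expect_true(df$dynamic)
    # two waves disjoint in time give two events inside their windows
    atlas <- fx$atlas
    wv2 <- waveSpec(rbind(c(60, 20), c(60, 55)), speedMmS = 0.35,
                    freqHz = 0.11, amplitudePct = 30, widthMm = 0.8,
                    tOnset = 420, nCycles = 1)
    r2 <- injectTravellingWave(fx$movie, atlas, wv2, fx$gt)
    es2 <- analyzeEvents(r2$movie)
    expect_identical(length(es2), 2L)
    df2 <- as.data.frame(es2)
    tr2 <- as.data.frame(r2$groundTruth)
    for (i in 1:2) {
        j <- which(df2$tStart >= tr2$tStart[i] - 1 &
                   df2$tEnd <= tr2$tEnd[i] + 1)
        expect_length(j, 1L)
    }
    # pure noise at z > 5: no false-positive events
    m0 <- simulateBaseline(fx$atlas, fx$spec, noiseDefaults(), seed = 77)
    expect_identical(length(analyzeEvents(m0)), 0L)
})

test_that("raising the z threshold does not create events", {
    fx <- oneWaveMovie(amp = 25, seed = 9)
    filt <- bandpassMovie(fx$movie, c(0.08, 0.15))
    rz <- robustZScore(filt, band = c(0.08, 0.15))
    counts <- vapply(c(3, 5, 7, 10), function(thr)
        length(detectEvents(rz$z, detectorConfig(zThreshold = thr),
                            fx$spec)), 1L)
    expect_true(all(diff(counts) <= 0))
})

test_that("propagation, delay and speed features follow their definitions", {
    # hand-built three-frame events with single-pixel footprints
    mkSet <- function(cols) {
        z <- array(0, c(30, 30, 10))
        ev <- list(id = 1L, tStart = 4L, tEnd = 6L, frames = 4:6,
                   footprints = list(), unionIdx = integer(), seed = c(10, cols[1], 4),
                   peakZ = 9)
        for (j in 1:3) {
            z[10, cols[j], 3 + j] <- 9
            ev$footprints[[j]] <- (cols[j] - 1L) * 30L + 10L
        }
        ev$unionIdx <- sort(unique(unlist(ev$footprints)))
        es <- new("EventSet", events = list(ev), dims = c(30L, 30L, 10L),
                  dt = 0.4, pixelMm = 0.1,
                  config = detectorConfig(zThreshold = 5))
        eventFeatures(es, NULL, z)
    }
    dyn <- classifyDynamic(mkSet(c(10, 13, 16)))   # steps of 3 px
    e <- eventRecords(dyn)[[1]]
    expect_equal(e$propagationPx, 6, tolerance = 1e-9)
    expect_true(e$dynamic)
    # the delay map orders pixels by their peak time
    expect_equal(e$delayMap$delaySec[order(e$delayMap$idx)], c(0, 0.4, 0.8))
    stat <- classifyDynamic(mkSet(c(10, 12, 14)))  # steps of 2 px
    expect_equal(eventRecords(stat)[[1]]$propagationPx, 4, tolerance = 1e-9)
    expect_false(eventRecords(stat)[[1]]$dynamic)
    # propagation oracle: stored track recomputation matches to 1e-9
    fx <- oneWaveMovie(speed = 0.5, amp = 30, seed = 21)
    es <- analyzeEvents(fx$movie)
    for (ev in eventRecords(es)) {
        tr <- ev$centroidTrack
        recomp <- sum(sqrt(rowSums(diff(tr[, 2:3, drop = FALSE])^2)))
        expect_lt(abs(ev$propagationPx - recomp), 1e-9)
        expect_equal(ev$propagationMm, ev$propagationPx * 0.1)
    }
})

test_that("single-frame events are degenerate with zero speed", {
    z <- array(0, c(30, 30, 6))
    z[10:14, 10:14, 3] <- 9
    ev <- list(id = 1L, tStart = 3L, tEnd = 3L, frames = 3L,
               footprints = list(as.integer(outer((10:14) - 1, 10:14 * 0 + 10,
                   function(c0, r) c0 * 30 + r))),
               unionIdx = integer(), seed = c(12, 12, 3), peakZ = 9)
    ev$footprints <- list(sort(unique(unlist(
        lapply(10:14, function(cc) (cc - 1L) * 30L + 10:14)))))
    ev$unionIdx <- ev$footprints[[1]]
    es <- new("EventSet", events = list(ev), dims = c(30L, 30L, 6L),
              dt = 0.4, pixelMm = 0.1, config = detectorConfig())
    es <- classifyDynamic(eventFeatures(es, NULL, z))
    e <- eventRecords(es)[[1]]
    expect_equal(e$propagationPx, 0)
    expect_equal(e$speedMmS, 0)
    expect_true(e$degenerate)
    expect_false(e$dynamic)
})

test_that("scan summaries average over dynamic events only", {
    mkEv <- function(id, dyn, amp, prop) list(
        id = id, tStart = 1L, tEnd = 5L, unionIdx = 1:20, peakZ = 8,
        propagationPx = prop, propagationMm = prop * 0.1,
        peakAmplitudePct = amp, durationS = 2, speedMmS = 0.3,
        dynamic = dyn, degenerate = FALSE,
        frames = 1:5, footprints = rep(list(1:4), 5),
        centroidTrack = cbind(1:5, 10, 10),
        delayMap = list(idx = 1:4, delaySec = rep(0, 4)))
    es <- new("EventSet", events = list(
        mkEv(1, TRUE, 20, 8), mkEv(2, TRUE, 30, 10), mkEv(3, TRUE, 10, 12),
        mkEv(4, FALSE, 50, 2)), dims = c(30L, 30L, 10L), dt = 0.4,
        pixelMm = 0.1, config = detectorConfig())
    s <- scanEventSummary(es)
    expect_equal(s$pctDynamic, 75)
    expect_equal(s$meanAmplitudePct, 20)      # dynamic events only
    expect_equal(s$meanPropagationMm, 1)
    allStatic <- es; allStatic@events <- lapply(allStatic@events, function(e) {
        e$dynamic <- FALSE; e })
    s0 <- scanEventSummary(allStatic)
    expect_equal(s0$pctDynamic, 0)
    expect_true(s0$undefinedMeans)
    empty <- new("EventSet", events = list(), dims = c(30L, 30L, 10L),
                 dt = 0.4, pixelMm = 0.1, config = detectorConfig())
    se <- scanEventSummary(empty)
    expect_identical(se$nEvents, 0L)
    expect_true(is.na(se$pctDynamic))
})
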