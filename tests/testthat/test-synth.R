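# Synthetic movie generator: atlas geometry, baseline noise, event
# injection, cohort and stimulation sessions, and the generator invariants
# (determinism, energy locality, path-length consistency, spectral
# placement).

test_that("atlas places all regions bilaterally and mirrors about the midline", {
    atlas <- buildAtlas(acquisitionSpec(128, 128, 10))
    lab <- atlasLabels(atlas)
    expect_setequal(unique(roiNames(atlas)), regionNamesCanonical())
    expect_length(roiIds(atlas), 18L)
    expect_true(all(table(lab[lab > 0]) >= 15))
    # every pixel is background or a named id
    expect_true(all(lab %in% c(0L, roiIds(atlas))))
    # mirror symmetry up to the left/right id swap (+/- 10)
    m <- lab[, ncol(lab):1]
    m[m > 0] <- ifelse(m[m > 0] > 10L, m[m > 0] - 10L, m[m > 0] + 10L)
    expect_identical(m, lab)
    expect_error(buildAtlas(acquisitionSpec(32, 128, 10)), "too small")
})

test_that("baseline simulation is deterministic with calibrated noise", {
    spec <- acquisitionSpec(64, 64, 3000)
    atlas <- buildAtlas(spec)
    nz <- list(whiteSd = 3, pinkSd = 0, pinkExponent = 1)
    m1 <- simulateBaseline(atlas, spec, nz, seed = 7)
    m2 <- simulateBaseline(atlas, spec, nz, seed = 7)
    expect_identical(movieData(m1), movieData(m2))
    # white-only noise: per-pixel temporal sd within 5% of nominal
    # (Monte-Carlo over 100 pixels, 3000 frames)
    sds <- apply(movieData(m1)[1:10, 1:10, ], c(1, 2), sd)
    expect_lt(abs(mean(sds) - 3) / 3, 0.05)
    # zero noise: every pixel constant, all values positive
    m0 <- simulateBaseline(atlas, spec, list(whiteSd = 0, pinkSd = 0,
                                             pinkExponent = 1), seed = 1)
    expect_equal(max(apply(movieData(m0)[1:4, 1:4, ], c(1, 2), sd)), 0)
    expect_true(all(movieData(m0) > 0))
    expect_error(simulateBaseline(atlas, spec,
                                  list(whiteSd = NA, pinkSd = 0,
                                       pinkExponent = 1), seed = 1),
                 "finite")
})

test_that("travelling wave injection follows the specified kinematics", {
    spec <- acquisitionSpec(96, 96, 700)
    atlas <- buildAtlas(spec)
    m0 <- simulateBaseline(atlas, spec, list(whiteSd = 0, pinkSd = 0,
                                             pinkExponent = 1), seed = 1)
    base <- movieData(m0)[, , 1]
    # speed 0.25 mm/s on a 0.1 mm / 0.4 s grid advances 1 px per frame
    wv <- waveSpec(rbind(c(30, 20), c(30, 70)), speedMmS = 0.25,
                   freqHz = 0.125, amplitudePct = 20, widthMm = 0.8,
                   tOnset = 50, nCycles = 2)
    r <- injectTravellingWave(m0, atlas, wv, emptyGroundTruth())
    g <- eventRecords(r$groundTruth)[[1]]
    expect_equal(diff(g$centroidTrack[, "col"]),
                 rep(1, nrow(g$centroidTrack) - 1), tolerance = 1e-12)
    # peak relative modulation equals amplitudePct within 1%
    rel <- movieData(r$movie) / rep(base, dim(r$movie)[3]) - 1
    expect_equal(max(rel), 0.20, tolerance = 0.05)
    # path-length consistency: logged length equals the track recomputation
    recomp <- sum(sqrt(rowSums(diff(g$centroidTrack[, 2:3])^2)))
    expect_lt(abs(g$pathLengthPx - recomp), 1e-9)
    # energy locality: frames before onset and pixels far from the path
    # are exactly baseline
    expect_identical(movieData(r$movie)[, , 1:49], movieData(m0)[, , 1:49])
    expect_identical(movieData(r$movie)[70:96, , ], movieData(m0)[70:96, , ])
    # error paths
    expect_error(injectTravellingWave(m0, atlas,
        waveSpec(rbind(c(-3, 2), c(30, 70))), emptyGroundTruth()), "inside")
    expect_error(injectTravellingWave(m0, atlas,
        waveSpec(rbind(c(30, 20), c(30, 70)), tOnset = 690, nCycles = 3),
        emptyGroundTruth()), "fit")
})

test_that("two identical waves with disjoint onsets superpose as a time shift", {
    spec <- acquisitionSpec(80, 80, 500)
    atlas <- buildAtlas(spec)
    m0 <- simulateBaseline(atlas, spec, list(whiteSd = 0, pinkSd = 0,
                                             pinkExponent = 1), seed = 1)
    path <- rbind(c(30, 20), c(30, 50))
    mk <- function(t0) waveSpec(path, speedMmS = 0.3, freqHz = 0.1,
                                amplitudePct = 15, widthMm = 0.8,
                                tOnset = t0, nCycles = 1)
    r <- injectTravellingWave(m0, atlas, mk(50), emptyGroundTruth())
    r <- injectTravellingWave(r$movie, atlas, mk(300), r$groundTruth)
    dev <- movieData(r$movie) / movieData(m0) - 1
    expect_equal(dev[, , 50:120], dev[, , 300:370], tolerance = 1e-10)
})

test_that("static events have zero path length and bounded support", {
    spec <- acquisitionSpec(80, 80, 300)
    atlas <- buildAtlas(spec)
    m0 <- simulateBaseline(atlas, spec, list(whiteSd = 0, pinkSd = 0,
                                             pinkExponent = 1), seed = 1)
    r <- injectStaticEvent(m0, atlas, c(30, 30), amplitudePct = 15,
                           durationFrames = 10, widthMm = 0.7, tOnset = 100,
                           groundTruth = emptyGroundTruth())
    g <- eventRecords(r$groundTruth)[[1]]
    expect_identical(g$pathLengthPx, 0)
    expect_false(g$dynamic)
    # time series at the centre returns exactly to baseline afterwards
    expect_identical(movieData(r$movie)[30, 30, 111:300],
                     movieData(m0)[30, 30, 111:300])
    # overlapping static + travelling events compose multiplicatively
    wv <- waveSpec(rbind(c(30, 25), c(30, 40)), speedMmS = 0.3, freqHz = 0.1,
                   amplitudePct = 20, widthMm = 0.8, tOnset = 95, nCycles = 1)
    r2 <- injectTravellingWave(r$movie, atlas, wv, r$groundTruth)
    rOnly <- injectTravellingWave(m0, atlas, wv, emptyGroundTruth())
    gainStatic <- movieData(r$movie) / movieData(m0)
    gainWave <- movieData(rOnly$movie) / movieData(m0)
    expect_equal(movieData(r2$movie), movieData(m0) * gainStatic * gainWave,
                 tolerance = 1e-12)
})

test_that("an injected noise-free wave train peaks at its carrier frequency", {
    spec <- acquisitionSpec(64, 64, 1000)
    atlas <- buildAtlas(spec)
    m0 <- simulateBaseline(atlas, spec, list(whiteSd = 0, pinkSd = 0,
                                             pinkExponent = 1), seed = 1)
    ctr <- roiCentroid(atlas, lookupRoi(atlas, "SecVisCtx", "left"))
    wv <- waveSpec(rbind(ctr, ctr + c(0, 8)), speedMmS = 0.2, freqHz = 0.125,
                   amplitudePct = 20, widthMm = 0.8, tOnset = 50,
                   nCycles = 10)
    r <- injectTravellingWave(m0, atlas, wv, emptyGroundTruth())
    tc <- roiTimecourses(r$movie, atlas, lookupRoi(atlas, "SecVisCtx", "left"))
    sp <- amplitudeSpectrum(tc[[3]], frameDt(r$movie))
    # above the infra-slow band of the train envelope itself, the spectrum
    # peaks at the carrier frequency (within one bin)
    sp <- sp[sp$freq >= 0.04, ]
    fpk <- sp$freq[which.max(sp$amplitude)]
    expect_lt(abs(fpk - 0.125), 1 / (1000 * 0.4) + 1e-9)
})

test_that("cohort arms implement the configured contrast", {
    spec <- acquisitionSpec(64, 64, 750)
    atlas <- buildAtlas(spec)
    co <- simulateCohort(2, c("VEH-like", "LPS-like"), spec, seed = 21,
                         atlas = atlas)
    arms <- vapply(co, function(s) s$arm, "")
    amps <- lapply(co, function(s) as.data.frame(s$groundTruth)$amplitudePct)
    expect_gt(mean(unlist(amps[arms == "LPS-like"])),
              mean(unlist(amps[arms == "VEH-like"])))
    # per-scan seeds differ -> distinct event timings
    t1 <- as.data.frame(co[[1]]$groundTruth)$tStart
    t2 <- as.data.frame(co[[2]]$groundTruth)$tStart
    expect_false(identical(t1, t2))
    # unknown arm name
    expect_error(cohortArmConfig("sham"), "unknown arm")
    # VEH arm only carries cortical medial/temporal wave patterns
    vehPat <- unlist(lapply(co[arms == "VEH-like"], function(s)
        as.data.frame(s$groundTruth)$pattern))
    expect_true(all(vehPat %in% c("MEDIO_TEMPORAL", "TEMPORO_MEDIAL",
                                  "UNCLASSIFIED_STATIC")))
})

test_that("injected event counts follow the configured Poisson rates", {
    spec <- acquisitionSpec(64, 64, 750)    # 5 min
    atlas <- buildAtlas(spec)
    cfg <- cohortArmConfig("VEH-like")
    counts <- vapply(seq_len(20), function(i) {
        st <- simulateScan(atlas, spec, cfg, seed = 400 + i)
        length(st$groundTruth)
    }, 1)
    lambda <- (cfg$waves$ratePerMin + cfg$statics$ratePerMin) * 5
    expect_lt(abs(mean(counts) - lambda),
              3 * sqrt(lambda / 20) + 0.5)  # Poisson error of the mean
})

test_that("stimulation sessions produce localized plateau responses", {
    spec <- acquisitionSpec(64, 64, 850)
    atlas <- buildAtlas(spec)
    nz <- list(whiteSd = 0, pinkSd = 0, pinkExponent = 1)
    resp <- list(regions = "PrimVisCtx", amplitudePct = 10,
                 riseS = 0.2, fallS = 0.2)
    st <- simulateStimSession(atlas, spec, response = resp, noise = nz,
                              seed = 2)
    tc <- roiTimecourses(st$movie, atlas)
    rel <- tc$PrimVisCtx_L / mean(tc$PrimVisCtx_L[1:70]) - 1
    # fast rise: block mean approaches the nominal 10%
    expect_gt(mean(rel[st$stim]) * 100, 9)
    expect_lt(mean(rel[st$stim]) * 100, 10 + 1e-6)
    # slow rise attenuates the block mean
    st2 <- simulateStimSession(atlas, spec,
                               response = modifyList(resp, list(riseS = 10)),
                               noise = nz, seed = 2)
    tc2 <- roiTimecourses(st2$movie, atlas)
    rel2 <- tc2$PrimVisCtx_L / mean(tc2$PrimVisCtx_L[1:70]) - 1
    expect_lt(mean(rel2[st2$stim]), mean(rel[st$stim]))
    # locality: non-target ROI flat in the zero-noise run
    expect_equal(sd(tc$Hippocampus_L), 0)
    # exactly 4 disjoint above-baseline epochs in the target ROI
    above <- rel > 1e-6
    runs <- rle(above)
    expect_identical(sum(runs$values), 4L)
    expect_error(simulateStimSession(atlas, acquisitionSpec(64, 64, 100),
                                     response = resp, noise = nz, seed = 1),
                 "exceeds")
    expect_error(simulateStimSession(atlas, spec,
        response = modifyList(resp, list(regions = "NoSuchRegion")),
        noise = nz, seed = 1), "no atlas region")
})
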