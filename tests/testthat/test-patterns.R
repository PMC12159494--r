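# Pattern taxonomy: delay-map features, SVD + k-means clustering on
# constructed separable instances, rule-based trajectory labelling with its
# direction antisymmetry, and proportion tables.

# build a minimal EventSet whose events carry prescribed delay maps
delayEventSet <- function(maps, dims = c(20L, 20L, 50L)) {
    evs <- lapply(seq_along(maps), function(i) {
        m <- maps[[i]]
        list(id = i, tStart = 1L, tEnd = 10L, frames = 1:2,
             footprints = list(m$idx, m$idx), unionIdx = m$idx,
             peakZ = 9, propagationPx = 10, propagationMm = 1,
             dynamic = TRUE, degenerate = FALSE,
             centroidTrack = cbind(1:2, 10, 10),
             delayMap = list(idx = m$idx, delaySec = m$delay,
                             peakZ = rep(9, length(m$idx))))
    })
    new("EventSet", events = evs, dims = dims, dt = 0.4, pixelMm = 0.1,
        config = detectorConfig())
}

rowBand <- function(row, cols, h = 20L) (cols - 1L) * h + row

test_that("delay features encode occupancy and directional slopes", {
    idx <- rowBand(10L, 5:15)
    maps <- list(
        list(idx = idx, delay = seq(0, 4, length.out = 11)),   # left -> right
        list(idx = idx, delay = seq(4, 0, length.out = 11)),   # reversed
        list(idx = idx, delay = rep(2, 11)))                   # static/uniform
    ft <- buildDelayFeatures(delayEventSet(maps), minAreaPx = 5)
    expect_identical(dim(ft$binary), c(3L, 400L))
    expect_true(all(ft$binary[1, idx] == 1))
    expect_gt(ft$direction[1, "horizontal"], 0)
    expect_equal(unname(ft$direction[1, "vertical"]), 0)
    expect_equal(ft$direction[2, ], -ft$direction[1, ], tolerance = 1e-12)
    expect_equal(unname(ft$direction[3, ]), c(0, 0))
    # small-footprint events are excluded
    tiny <- list(list(idx = idx[1:3], delay = c(0, 1, 2)))
    expect_error(buildDelayFeatures(delayEventSet(tiny), minAreaPx = 5),
                 "no events")
})

test_that("k-means on SVD scores separates disjoint spatial zones exactly", {
    zones <- list(rowBand(4L, 2:8), rowBand(4L, 12:18),
                  rowBand(16L, 2:8), rowBand(16L, 12:18))
    maps <- list()
    for (z in seq_along(zones)) {
        for (i in 1:10) {
            dirSign <- if (i %% 2 == 0) 1 else -1
            maps[[length(maps) + 1]] <- list(
                idx = zones[[z]],
                delay = dirSign * seq(0, 3, length.out = 7))
        }
    }
    truth <- rep(1:4, each = 10)
    ft <- buildDelayFeatures(delayEventSet(maps), minAreaPx = 5)
    cl <- clusterPatterns(ft, kSpatial = 4, seed = 11)
    # label-permutation-invariant perfect recovery (Rand index 1)
    expect_identical(length(unique(paste(truth, cl$spatial))), 4L)
    # directional subclusters split the two delay directions
    for (z in 1:4) {
        ii <- which(truth == z)
        sub <- cl$directional[ii]
        expect_identical(length(unique(paste(rep(c(2, 1), 5), sub))), 2L)
    }
    # duplicated rows land in the same cluster; same seed reproduces
    expect_identical(cl$spatial[1], cl$spatial[which(truth == 1)[3] ])
    cl2 <- clusterPatterns(ft, kSpatial = 4, seed = 11)
    expect_identical(cl, cl2)
    expect_error(clusterPatterns(
        buildDelayFeatures(delayEventSet(maps[1:3]), 5), kSpatial = 4),
        "at least 4 events")
})

test_that("trajectory labels recover all six simulated patterns", {
    spec <- acquisitionSpec(80, 80, 400)
    set.seed(1)
    six <- simulateSixPatternCohort(spec, nPerPattern = 4, seed = 11)
    es <- analyzeEvents(six$movie, detectorConfig(minNoiseSd = 0.5))
    es <- labelPatterns(es, six$atlas)
    expect_gte(labelRecovery(es, six$groundTruth), 0.95)
    # a static event is UNCLASSIFIED_STATIC by rule
    stat <- delayEventSet(list(list(idx = rowBand(10L, 5:15, h = 80L),
                                    delay = rep(1, 11))),
                          dims = c(80L, 80L, 50L))
    stat@events[[1]]$dynamic <- FALSE
    stat <- labelPatterns(stat, buildAtlas(acquisitionSpec(80, 80, 10)))
    expect_identical(eventRecords(stat)[[1]]$pattern, "UNCLASSIFIED_STATIC")
    # atlas without hemisphere info is rejected
    bare <- new("RoiAtlas", labels = matrix(0L, 80, 80),
                regionNames = character(), hemispheres = character())
    dyn <- delayEventSet(list(list(idx = rowBand(10L, 5:15, h = 80L),
                                   delay = rep(1, 11))),
                         dims = c(80L, 80L, 50L))
    expect_error(labelPatterns(dyn, bare), "hemisphere")
})

test_that("time reversal swaps the direction-paired labels", {
    spec <- acquisitionSpec(80, 80, 400)
    set.seed(5)
    six <- simulateSixPatternCohort(spec, nPerPattern = 3, seed = 42)
    cfg <- detectorConfig(minNoiseSd = 0.5)
    lab1 <- as.data.frame(labelPatterns(analyzeEvents(six$movie, cfg),
                                        six$atlas))
    rev3 <- movieData(six$movie)[, , rev(seq_len(dim(six$movie)[3]))]
    labR <- as.data.frame(labelPatterns(
        analyzeEvents(fusMovie(rev3, movieSpec(six$movie)), cfg), six$atlas))
    swap <- c(MEDIO_TEMPORAL = "TEMPORO_MEDIAL",
              TEMPORO_MEDIAL = "MEDIO_TEMPORAL",
              CORTICO_HIPPOCAMPAL = "HIPPOCAMPO_CORTICAL",
              HIPPOCAMPO_CORTICAL = "CORTICO_HIPPOCAMPAL",
              TRANSHEMISPHERIC = "TRANSHEMISPHERIC",
              CORTICO_SUBCORTICAL = "CORTICO_SUBCORTICAL",
              UNCLASSIFIED_STATIC = "UNCLASSIFIED_STATIC")
    t1 <- table(factor(unname(swap[lab1$pattern]), levels = patternLabels()))
    t2 <- table(factor(labR$pattern, levels = patternLabels()))
    expect_identical(as.integer(t1), as.integer(t2))
})

test_that("pattern proportion tables normalise correctly", {
    labels <- data.frame(
        scan = c("s1", "s1", rep("s2", 4)),
        pattern = c("MEDIO_TEMPORAL", "UNCLASSIFIED_STATIC",
                    "MEDIO_TEMPORAL", "TEMPORO_MEDIAL",
                    "UNCLASSIFIED_STATIC", "UNCLASSIFIED_STATIC"))
    pf <- patternFrequencies(labels, scans = c("s1", "s2", "s3"))
    s1 <- pf$all[pf$all$scan == "s1", ]
    expect_equal(s1$pct[s1$pattern == "MEDIO_TEMPORAL"], 50)
    expect_equal(s1$pct[s1$pattern == "UNCLASSIFIED_STATIC"], 50)
    t1 <- pf$travellingOnly[pf$travellingOnly$scan == "s1", ]
    expect_equal(t1$pct[t1$pattern == "MEDIO_TEMPORAL"], 100)
    # percentages sum to 100 within 1e-9 for every scan and table
    for (tab in pf[c("all", "travellingOnly")])
        for (s in unique(tab$scan))
            expect_lt(abs(sum(tab$pct[tab$scan == s]) - 100), 1e-9)
    expect_identical(pf$empty, "s3")
    # permutation invariance of the proportions
    perm <- labels[sample(nrow(labels)), ]
    pf2 <- patternFrequencies(perm, scans = c("s1", "s2", "s3"))
    expect_equal(pf$all, pf2$all)
})
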