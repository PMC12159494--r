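# Shared fixtures and independent oracles, built in code at test time.

# small acquisition defaults used across tests
tinySpec <- function(h = 64L, w = 64L, T = 600L) acquisitionSpec(h, w, T)

# noiseless baseline + one injected wave, for feature tests
oneWaveMovie <- function(speed = 0.4, freq = 0.1, amp = 30, tOnset = 100,
                         nCycles = 1, noise = noiseDefaults(), seed = 3,
                         spec = acquisitionSpec(96, 96, 700)) {
    atlas <- buildAtlas(spec)
    m <- simulateBaseline(atlas, spec, noise, seed = seed)
    wv <- waveSpec(rbind(c(30, 20), c(30, 60)), speedMmS = speed,
                   freqHz = freq, amplitudePct = amp, widthMm = 0.8,
                   tOnset = tOnset, nCycles = nCycles)
    r <- injectTravellingWave(m, atlas, wv, emptyGroundTruth())
    list(movie = r$movie, gt = r$groundTruth, atlas = atlas, spec = spec)
}

# brute-force flood fill over a thresholded z-array with the detector's
# connectivity (8-neighbour within a frame, same-pixel across frames);
# returns a list of sorted voxel-index sets
floodFillOracle <- function(mask) {
    d <- dim(mask)
    lab <- array(0L, d)
    idx <- which(mask)
    nxt <- 0L
    for (start in idx) {
        if (lab[start] > 0L) next
        nxt <- nxt + 1L
        queue <- start
        lab[start] <- nxt
        while (length(queue)) {
            v <- queue[[1]]; queue <- queue[-1]
            rc <- arrayInd(v, d)
            for (dr in -1:1) for (dc in -1:1) for (dtt in -1:1) {
                if (dtt != 0 && (dr != 0 || dc != 0)) next  # temporal: same pixel
                if (dr == 0 && dc == 0 && dtt == 0) next
                r2 <- rc[1] + dr; c2 <- rc[2] + dc; t2 <- rc[3] + dtt
                if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2] ||
                    t2 < 1 || t2 > d[3]) next
                u <- (t2 - 1L) * d[1] * d[2] + (c2 - 1L) * d[1] + r2
                if (mask[u] && lab[u] == 0L) {
                    lab[u] <- nxt
                    queue <- c(queue, u)
                }
            }
        }
    }
    comps <- split(idx, lab[idx])
    lapply(unname(comps), sort)
}

# voxel sets of an EventSet, in the oracle's format
eventVoxelSets <- function(es) {
    d <- es@dims
    out <- lapply(es@events, function(e) {
        v <- unlist(lapply(seq_along(e$frames), function(j)
            (e$frames[j] - 1L) * d[1] * d[2] + e$footprints[[j]]))
        sort(unname(v))
    })
    out[order(vapply(out, min, 1))]
}

# per-truth label recovery fraction on a six-pattern cohort analysis
labelRecovery <- function(es, gt) {
    mt <- matchEventsToTruth(es, gt)
    tr <- as.data.frame(gt)
    df <- as.data.frame(es)
    pe <- mt$truth$primaryEvent
    ok <- !is.na(pe)
    mean(df$pattern[pe[ok]] == tr$pattern[ok])
}
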