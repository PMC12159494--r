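# End-to-end orchestration: resting-state analysis (fALFF, static FC and
# group differences, PCA modes, event detection and pattern taxonomy,
# dynamic seed FC) and stimulation-block analysis, with CSV/JSON artefacts
# and a run manifest. A simulate-then-analyse demo mode exercises the whole
# pipeline on a small synthetic cohort.

.stageLog <- function(verbose, stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Resting-state analysis of one or more groups of scans
#'
#' For every scan: fALFF map and per-ROI table, wide-band ROI time courses
#' and static FC, wave-band event detection with features, dynamic/static
#' classification and pattern labels. Per group: mean-covariance PCA modes
#' and scree, pattern proportions, and (between the first two groups) the
#' Fisher-z FC difference. A representative dynamic seed-FC trace is
#' computed per group (right primary visual cortex seed, left visual cortex
#' target). All tables are written under `outDir` together with a manifest
#' recording configuration and seed.
#'
#' @param groups named list; each element is a list of [FusMovie-class].
#' @param atlas a [RoiAtlas-class].
#' @param outDir output directory (created).
#' @param wideBand,waveBand analysis bands in Hz.
#' @param detector [detectorConfig()].
#' @param eigenvalueMin,nDisplay PCA retention settings.
#' @param falffThreshold fALFF mask threshold.
#' @param seed seed recorded in the manifest.
#' @param verbose log one line per stage.
#' @return invisible list with all per-scan and group results.
#' @export
runResting <- function(groups, atlas, outDir, wideBand = c(0.0008, 0.2),
                       waveBand = c(0.08, 0.15),
                       detector = detectorConfig(band = waveBand),
                       eigenvalueMin = 0.1, nDisplay = 10L,
                       falffThreshold = 0.075, seed = NA_integer_,
                       verbose = TRUE) {
    if (is.null(names(groups)) || !length(groups))
        stop("groups must be a named list of scan lists")
    if (is.null(atlas)) stop("preprocessing stage: no atlas supplied")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    res <- list(groups = list())
    falffRows <- list(); summaryRows <- list(); labelRows <- list()
    for (g in names(groups)) {
        scans <- groups[[g]]
        fcs <- list()
        for (si in seq_along(scans)) {
            scanId <- paste0(g, "_scan", si)
            mv <- scans[[si]]
            .stageLog(verbose, "falff", "%s: %d x %d x %d", scanId,
                      dim(mv)[1], dim(mv)[2], dim(mv)[3])
            fa <- falffMap(mv, atlas, band = waveBand,
                           threshold = falffThreshold)
            falffRows[[scanId]] <- cbind(scan = scanId, group = g, fa$roi)
            .stageLog(verbose, "static-fc", "%s", scanId)
            wide <- bandpassMovie(mv, wideBand)
            fcs[[si]] <- staticFC(roiTimecourses(wide, atlas))
            .stageLog(verbose, "events", "%s", scanId)
            es <- analyzeEvents(mv, detector)
            es <- labelPatterns(es, atlas)
            summaryRows[[scanId]] <- cbind(scan = scanId, group = g,
                                           scanEventSummary(es))
            df <- as.data.frame(es)
            if (nrow(df))
                labelRows[[scanId]] <- cbind(scan = scanId, group = g, df)
            res$groups[[g]]$events[[si]] <- es
        }
        .stageLog(verbose, "pca", "group %s (%d scans)", g, length(scans))
        res$groups[[g]]$fc <- fcs
        res$groups[[g]]$modes <- pcaModes(scans, band = wideBand,
                                          eigenvalueMin = eigenvalueMin,
                                          nDisplay = nDisplay)
        .stageLog(verbose, "dyn-fc", "group %s", g)
        waveFilt <- bandpassMovie(scans[[1]], waveBand)
        res$groups[[g]]$dynFC <- dynamicSeedFC(
            waveFilt, atlas,
            seedRoi = lookupRoi(atlas, "PrimVisCtx", "right"),
            targetRoi = lookupRoi(atlas, c("PrimVisCtx", "SecVisCtx"), "left"))
        ev <- res$groups[[g]]$modes@eigenvalues
        utils::write.csv(data.frame(
            component = seq_along(ev), eigenvalue = ev,
            explained = res$groups[[g]]$modes@explained,
            cumulative = cumsum(res$groups[[g]]$modes@explained)),
            file.path(outDir, paste0("scree_", g, ".csv")), row.names = FALSE)
    }
    falffTab <- do.call(rbind, falffRows)
    utils::write.csv(falffTab, file.path(outDir, "falff_roi.csv"),
                     row.names = FALSE)
    sumTab <- do.call(rbind, summaryRows)
    utils::write.csv(sumTab, file.path(outDir, "event_summary.csv"),
                     row.names = FALSE)
    labTab <- if (length(labelRows)) do.call(rbind, labelRows) else NULL
    if (!is.null(labTab))
        utils::write.csv(labTab, file.path(outDir, "events.csv"),
                         row.names = FALSE)
    if (!is.null(labTab)) {
        pf <- patternFrequencies(data.frame(scan = labTab$scan,
                                            pattern = labTab$pattern),
                                 scans = unique(sumTab$scan))
        if (!is.null(pf$all))
            utils::write.csv(pf$all, file.path(outDir, "pattern_proportions.csv"),
                             row.names = FALSE)
        res$patterns <- pf
    }
    if (length(groups) >= 2L) {
        gA <- names(groups)[1]; gB <- names(groups)[2]
        dz <- fcDifference(res$groups[[gB]]$fc, res$groups[[gA]]$fc)
        ids <- dz$roiIds
        long <- expand.grid(roi_a = ids, roi_b = ids, stringsAsFactors = FALSE)
        long$delta_z <- as.numeric(dz$deltaZ)
        long$delta_r <- as.numeric(dz$deltaR)
        utils::write.csv(long[long$roi_a < long$roi_b, ],
                         file.path(outDir, paste0("fc_difference_", gB,
                                                  "_minus_", gA, ".csv")),
                         row.names = FALSE)
        res$fcDifference <- dz
    }
    res$falff <- falffTab
    res$summary <- sumTab
    manifest <- list(seed = seed, wideBand = wideBand, waveBand = waveBand,
                     detector = detector, eigenvalueMin = eigenvalueMin,
                     nDisplay = nDisplay, falffThreshold = falffThreshold,
                     groups = lapply(groups, length),
                     package = as.character(utils::packageVersion("fuswaves")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(res)
}

#' Stimulation-block analysis
#'
#' ΔCBV% is computed against the initial rest period; the per-ROI time
#' courses of the four (in general `nBlocks`) stimulation blocks are
#' aligned on block onset and averaged, and the scalar response per ROI is
#' the mean ΔCBV% over the stimulation epochs.
#'
#' @param movie a raw [FusMovie-class] covering the protocol.
#' @param atlas a [RoiAtlas-class].
#' @param protocol a [StimulusProtocol-class].
#' @param ids ROI ids to report (default all).
#' @param outDir optional output directory for CSVs.
#' @return list with `blockAverage` (data.frame, time from block onset and
#'   one column per ROI), `response` (data.frame `roi`, `meanDeltaCbvPct`)
#'   and `stim` (logical per frame).
#' @export
runStim <- function(movie, atlas, protocol = stimulusProtocol(),
                    ids = roiIds(atlas), outDir = NULL) {
    spec <- movie@spec
    dt <- spec@dt
    if (protocolDuration(protocol) > spec@nFrames * dt)
        stop("protocol exceeds the record")
    nRest <- max(2L, round(protocol@initialRestS / dt))
    pct <- percentChange(movie, baseline = c(1L, nRest))
    tc <- roiTimecourses(pct, atlas, ids)
    cols <- setdiff(names(tc), c("frame", "time_s"))
    tsec <- tc$time_s
    blockLenF <- round((protocol@stimDurS + protocol@restBetweenS) / dt)
    stim <- rep(FALSE, spec@nFrames)
    onsets <- integer(protocol@nBlocks)
    for (b in seq_len(protocol@nBlocks)) {
        onS <- protocol@initialRestS +
            (b - 1) * (protocol@stimDurS + protocol@restBetweenS)
        onsets[b] <- round(onS / dt) + 1L
        stim <- stim | (tsec >= onS & tsec < onS + protocol@stimDurS)
    }
    avg <- matrix(0, blockLenF, length(cols), dimnames = list(NULL, cols))
    nUsed <- 0L
    for (b in onsets) {
        if (b + blockLenF - 1L > spec@nFrames) next
        avg <- avg + as.matrix(tc[b:(b + blockLenF - 1L), cols])
        nUsed <- nUsed + 1L
    }
    if (!nUsed) stop("no complete stimulation block fits the record")
    avg <- avg / nUsed
    blockAverage <- data.frame(time_s = (seq_len(blockLenF) - 1) * dt, avg,
                               check.names = FALSE)
    response <- data.frame(
        roi = cols,
        meanDeltaCbvPct = vapply(cols, function(cn) mean(tc[[cn]][stim]),
                                 numeric(1)),
        row.names = NULL)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(blockAverage,
                         file.path(outDir, "stim_block_average.csv"),
                         row.names = FALSE)
        utils::write.csv(response, file.path(outDir, "stim_response.csv"),
                         row.names = FALSE)
    }
    list(blockAverage = blockAverage, response = response, stim = stim)
}

#' Simulate-then-analyse demo
#'
#' Simulates a small two-arm cohort (VEH-like and LPS-like) and runs the
#' full resting-state analysis on it.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param nScans scans per arm.
#' @param height,width,nFrames grid of the demo scans.
#' @param verbose log stages.
#' @return invisible [runResting()] result (with `cohort` attached).
#' @export
runDemo <- function(outDir, seed = 1L, nScans = 3L, height = 64L,
                    width = 64L, nFrames = 1500L, verbose = TRUE) {
    spec <- acquisitionSpec(height, width, nFrames)
    atlas <- buildAtlas(spec)
    .stageLog(verbose, "simulate", "%d scans per arm, %d x %d x %d",
              nScans, height, width, nFrames)
    cohort <- simulateCohort(nScans, c("VEH-like", "LPS-like"), spec,
                             seed = seed, atlas = atlas)
    groups <- list(
        "VEH-like" = lapply(Filter(function(s) s$arm == "VEH-like", cohort),
                            function(s) s$movie),
        "LPS-like" = lapply(Filter(function(s) s$arm == "LPS-like", cohort),
                            function(s) s$movie))
    res <- runResting(groups, atlas, outDir, seed = seed, verbose = verbose)
    res$cohort <- cohort
    invisible(res)
}
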