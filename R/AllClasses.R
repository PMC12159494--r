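# Central S4 containers. Movies are (row, col, frame) arrays of nonnegative
# Power Doppler intensity; row 1 is dorsal (top), column 1 is left, and the
# atlas midline runs between columns width/2 and width/2 + 1.

#' Acquisition geometry and timing of a functional ultrasound movie
#'
#' Describes the fixed acquisition constants of a CBV movie: grid size,
#' number of frames, frame period `dt` (seconds) and pixel pitch `pixelMm`
#' (millimetres). The defaults correspond to a 20-min resting-state
#' acquisition sampled every 0.4 s at 100 um resolution.
#'
#' @slot height,width image grid size in pixels.
#' @slot nFrames number of frames.
#' @slot dt frame period in seconds.
#' @slot pixelMm pixel pitch in millimetres.
#' @export
setClass("AcquisitionSpec",
    representation(height = "integer", width = "integer", nFrames = "integer",
                   dt = "numeric", pixelMm = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
        if (object@pixelMm <= 0) msg <- c(msg, "pixelMm must be > 0")
        if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
        if (object@height < 1L || object@width < 1L)
            msg <- c(msg, "height and width must be positive")
        if (length(msg)) msg else TRUE
    })

#' @param height,width,nFrames,dt,pixelMm see slot documentation.
#' @return An `AcquisitionSpec` object.
#' @rdname AcquisitionSpec-class
#' @examples
#' acquisitionSpec(128, 128, 3000)
#' @export
acquisitionSpec <- function(height = 128L, width = 128L, nFrames = 3000L,
                            dt = 0.4, pixelMm = 0.1) {
    new("AcquisitionSpec", height = as.integer(height),
        width = as.integer(width), nFrames = as.integer(nFrames),
        dt = as.numeric(dt), pixelMm = as.numeric(pixelMm))
}

setMethod("show", "AcquisitionSpec", function(object) {
    cat(sprintf("AcquisitionSpec: %d x %d px, %d frames, dt = %g s (%.1f min), pixel = %g mm\n",
                object@height, object@width, object@nFrames, object@dt,
                object@nFrames * object@dt / 60, object@pixelMm))
})

#' Power Doppler CBV movie
#'
#' A 3-D stack of Power Doppler intensity (proportional to cerebral blood
#' volume), dimension `(row, col, frame)`, together with its
#' [AcquisitionSpec-class].
#'
#' @slot data numeric array `(height, width, nFrames)`.
#' @slot spec the [AcquisitionSpec-class].
#' @export
setClass("FusMovie",
    representation(data = "array", spec = "AcquisitionSpec"),
    validity = function(object) {
        d <- dim(object@data)
        s <- object@spec
        if (length(d) != 3L)
            return("data must be a 3-D (row, col, frame) array")
        if (d[1] != s@height || d[2] != s@width || d[3] != s@nFrames)
            return("data dimensions do not match the acquisition spec")
        if (anyNA(object@data)) return("data contains missing values")
        TRUE
    })

#' @param data 3-D array `(row, col, frame)`.
#' @param spec an [AcquisitionSpec-class]; if `NULL`, one is derived from
#'   `dim(data)` with the supplied `dt` and `pixelMm`.
#' @param dt,pixelMm used only when `spec` is `NULL`.
#' @return A `FusMovie`.
#' @rdname FusMovie-class
#' @export
fusMovie <- function(data, spec = NULL, dt = 0.4, pixelMm = 0.1) {
    if (is.null(spec)) {
        d <- dim(data)
        spec <- acquisitionSpec(d[1], d[2], d[3], dt = dt, pixelMm = pixelMm)
    }
    new("FusMovie", data = data, spec = spec)
}

setMethod("show", "FusMovie", function(object) {
    cat("FusMovie\n  ")
    show(object@spec)
    cat(sprintf("  intensity range [%.3g, %.3g]\n",
                min(object@data), max(object@data)))
})

setMethod("dim", "FusMovie", function(x) dim(x@data))

#' Integer region-of-interest label atlas
#'
#' A 2-D integer label map (0 = background) with a name and a hemisphere
#' (`"left"`/`"right"`) per label id. Labels come in mirrored left/right
#' pairs about the vertical midline of the image.
#'
#' @slot labels integer matrix, 0 = background.
#' @slot regionNames named character vector, names are label ids as strings.
#' @slot hemispheres named character vector (`"left"`/`"right"`), same names.
#' @export
setClass("RoiAtlas",
    representation(labels = "matrix", regionNames = "character",
                   hemispheres = "character"),
    validity = function(object) {
        ids <- names(object@regionNames)
        if (anyDuplicated(ids)) return("label ids must be unique")
        if (!identical(sort(ids), sort(names(object@hemispheres))))
            return("regionNames and hemispheres must cover the same ids")
        if (!all(object@hemispheres %in% c("left", "right")))
            return("hemispheres must be 'left' or 'right'")
        present <- unique(as.integer(object@labels))
        if (!all(as.integer(ids) %in% present))
            return("every named id must occur in the label map")
        if (!all(present %in% c(0L, as.integer(ids))))
            return("label map contains ids without a name entry")
        TRUE
    })

setMethod("show", "RoiAtlas", function(object) {
    cat(sprintf("RoiAtlas: %d x %d px, %d regions (%d per hemisphere)\n",
                nrow(object@labels), ncol(object@labels),
                length(object@regionNames),
                sum(object@hemispheres == "left")))
})

#' Specification of one injected travelling wave
#'
#' Defines a quasi-sinusoidal travelling CBV wave: a Gaussian spatial bump
#' (sd `widthMm`) whose centre advances along `path` at `speedMmS`, carrying
#' a raised-cosine (nonnegative) oscillation at `freqHz` with peak relative
#' amplitude `amplitudePct` (% of baseline CBV).
#'
#' @slot pattern trajectory class, one of [patternLabels()].
#' @slot path numeric matrix of `(row, col)` waypoints.
#' @slot speedMmS propagation speed in mm/s (typical vasomotor range 0.1-0.8).
#' @slot freqHz carrier frequency in Hz (vasomotor band 0.08-0.15).
#' @slot amplitudePct peak relative CBV amplitude in percent.
#' @slot widthMm Gaussian footprint sd in millimetres.
#' @slot tOnset first active frame (1-based).
#' @slot nCycles number of carrier cycles.
#' @export
setClass("WaveSpec",
    representation(pattern = "character", path = "matrix", speedMmS = "numeric",
                   freqHz = "numeric", amplitudePct = "numeric",
                   widthMm = "numeric", tOnset = "numeric", nCycles = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@speedMmS <= 0) msg <- c(msg, "speedMmS must be positive")
        if (object@freqHz <= 0) msg <- c(msg, "freqHz must be positive")
        if (object@amplitudePct <= 0) msg <- c(msg, "amplitudePct must be positive")
        if (object@widthMm <= 0) msg <- c(msg, "widthMm must be positive")
        if (ncol(object@path) != 2L) msg <- c(msg, "path must be (row, col) waypoints")
        if (length(msg)) msg else TRUE
    })

#' @param pattern,path,speedMmS,freqHz,amplitudePct,widthMm,tOnset,nCycles
#'   see slot documentation.
#' @rdname WaveSpec-class
#' @export
waveSpec <- function(path, speedMmS = 0.3, freqHz = 0.125, amplitudePct = 20,
                     widthMm = 0.8, tOnset = 1, nCycles = 2,
                     pattern = "UNCLASSIFIED_STATIC") {
    new("WaveSpec", pattern = pattern, path = as.matrix(path),
        speedMmS = speedMmS, freqHz = freqHz, amplitudePct = amplitudePct,
        widthMm = widthMm, tOnset = as.numeric(tOnset), nCycles = nCycles)
}

#' Registry of the events injected by the simulator
#'
#' One entry per injected event, carrying the generating parameters, the true
#' per-frame centroid track, the true path length (sum of consecutive centroid
#' displacements, pixels), the true dynamic flag and the expected detector
#' peak z-score. Used as ground truth in parameter-recovery tests.
#'
#' @slot events list of per-event records.
#' @export
setClass("GroundTruthLog", representation(events = "list"))

#' @return An empty `GroundTruthLog`.
#' @rdname GroundTruthLog-class
#' @export
emptyGroundTruth <- function() new("GroundTruthLog", events = list())

setMethod("show", "GroundTruthLog", function(object) {
    cat(sprintf("GroundTruthLog: %d injected events (%d dynamic)\n",
                length(object@events),
                sum(vapply(object@events, function(e) isTRUE(e$dynamic), TRUE))))
})

setMethod("length", "GroundTruthLog", function(x) length(x@events))

#' @param x a `GroundTruthLog`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @rdname GroundTruthLog-class
#' @export
as.data.frame.GroundTruthLog <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    if (!length(x@events)) {
        return(data.frame(id = integer(), kind = character(),
                          pattern = character(), tStart = numeric(),
                          tEnd = numeric(), amplitudePct = numeric(),
                          freqHz = numeric(), speedMmS = numeric(),
                          pathLengthPx = numeric(), dynamic = logical(),
                          peakZ = numeric()))
    }
    do.call(rbind, lapply(x@events, function(e)
        data.frame(id = e$id, kind = e$kind, pattern = e$pattern,
                   tStart = e$tStart, tEnd = e$tEnd,
                   amplitudePct = e$amplitudePct,
                   freqHz = if (is.null(e$freqHz)) NA_real_ else e$freqHz,
                   speedMmS = if (is.null(e$speedMmS)) NA_real_ else e$speedMmS,
                   pathLengthPx = e$pathLengthPx, dynamic = e$dynamic,
                   peakZ = if (is.null(e$peakZ)) NA_real_ else e$peakZ)))
}

#' Visual stimulation protocol
#'
#' Block design: an initial rest in the dark followed by `nBlocks`
#' stimulation blocks (flickering at `flickerHz`), each followed by a rest
#' period. Defaults: 30 s rest, 4 blocks of 30 s at 3 Hz separated by 45 s.
#'
#' @slot initialRestS,stimDurS,restBetweenS durations in seconds.
#' @slot nBlocks number of stimulation blocks.
#' @slot flickerHz flicker frequency (annotation only).
#' @export
setClass("StimulusProtocol",
    representation(initialRestS = "numeric", nBlocks = "integer",
                   stimDurS = "numeric", restBetweenS = "numeric",
                   flickerHz = "numeric"),
    validity = function(object) {
        if (object@initialRestS <= 0 || object@stimDurS <= 0 ||
            object@restBetweenS <= 0)
            return("all durations must be positive")
        if (object@nBlocks < 1L) return("nBlocks must be >= 1")
        TRUE
    })

#' @param initialRestS,nBlocks,stimDurS,restBetweenS,flickerHz see slots.
#' @rdname StimulusProtocol-class
#' @export
stimulusProtocol <- function(initialRestS = 30, nBlocks = 4L, stimDurS = 30,
                             restBetweenS = 45, flickerHz = 3) {
    new("StimulusProtocol", initialRestS = initialRestS,
        nBlocks = as.integer(nBlocks), stimDurS = stimDurS,
        restBetweenS = restBetweenS, flickerHz = flickerHz)
}

#' @param protocol a `StimulusProtocol`.
#' @return total protocol duration in seconds.
#' @rdname StimulusProtocol-class
#' @export
protocolDuration <- function(protocol) {
    protocol@initialRestS +
        protocol@nBlocks * (protocol@stimDurS + protocol@restBetweenS)
}

setMethod("show", "StimulusProtocol", function(object) {
    cat(sprintf("StimulusProtocol: %gs rest + %d x (%gs stim @ %g Hz + %gs rest) = %gs\n",
                object@initialRestS, object@nBlocks, object@stimDurS,
                object@flickerHz, object@restBetweenS,
                protocolDuration(object)))
})

#' Detected spatiotemporal CBV events
#'
#' Container for the events found by [detectEvents()] in one movie, each a
#' list with frame range, per-frame footprints, seed voxel, centroid track,
#' propagation (sum of centroid displacements), peak amplitude, delay map
#' and mean centroid speed. `as.data.frame` flattens the scalar features.
#'
#' @slot events list of per-event records.
#' @slot dims `(height, width, nFrames)` of the source movie.
#' @slot dt frame period (s).
#' @slot pixelMm pixel pitch (mm).
#' @slot config the `DetectorConfig` list used.
#' @export
setClass("EventSet",
    representation(events = "list", dims = "integer", dt = "numeric",
                   pixelMm = "numeric", config = "list"))

setMethod("show", "EventSet", function(object) {
    n <- length(object@events)
    nd <- sum(vapply(object@events, function(e) isTRUE(e$dynamic), TRUE))
    cat(sprintf("EventSet: %d events (%d dynamic) on a %d x %d x %d movie\n",
                n, nd, object@dims[1], object@dims[2], object@dims[3]))
})

setMethod("length", "EventSet", function(x) length(x@events))

#' @param x an `EventSet`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @rdname EventSet-class
#' @export
as.data.frame.EventSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    if (!length(x@events)) {
        return(data.frame(id = integer(), tStart = integer(), tEnd = integer(),
                          nPx = integer(), peakZ = numeric(),
                          propagationPx = numeric(), propagationMm = numeric(),
                          peakAmplitudePct = numeric(), durationS = numeric(),
                          speedMmS = numeric(), dynamic = logical(),
                          pattern = character()))
    }
    do.call(rbind, lapply(x@events, function(e)
        data.frame(id = e$id, tStart = e$tStart, tEnd = e$tEnd,
                   nPx = length(e$unionIdx), peakZ = e$peakZ,
                   propagationPx = if (is.null(e$propagationPx)) NA_real_ else e$propagationPx,
                   propagationMm = if (is.null(e$propagationMm)) NA_real_ else e$propagationMm,
                   peakAmplitudePct = if (is.null(e$peakAmplitudePct)) NA_real_ else e$peakAmplitudePct,
                   durationS = if (is.null(e$durationS)) NA_real_ else e$durationS,
                   speedMmS = if (is.null(e$speedMmS)) NA_real_ else e$speedMmS,
                   dynamic = if (is.null(e$dynamic)) NA else e$dynamic,
                   pattern = if (is.null(e$pattern)) NA_character_ else e$pattern)))
}

#' Static functional connectivity matrix
#'
#' Pairwise Pearson correlations between ROI time courses, with the Fisher
#' z-transformed copy (`atanh` of r clipped away from +/-1).
#'
#' @slot roiIds character vector of ROI identifiers.
#' @slot r symmetric correlation matrix, unit diagonal.
#' @slot z Fisher-transformed copy.
#' @export
setClass("FcMatrix",
    representation(roiIds = "character", r = "matrix", z = "matrix"),
    validity = function(object) {
        if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-8)))
            return("r must be symmetric")
        if (any(object@r < -1 - 1e-12 | object@r > 1 + 1e-12))
            return("r must lie in [-1, 1]")
        TRUE
    })

setMethod("show", "FcMatrix", function(object) {
    cat(sprintf("FcMatrix: %d ROIs, mean off-diagonal r = %.3f\n",
                length(object@roiIds),
                mean(object@r[upper.tri(object@r)])))
})

#' Oscillatory modes from a group-mean covariance PCA
#'
#' Eigen-decomposition of the pixelwise covariance averaged over the
#' acquisitions of a group: descending eigenvalues, orthonormal spatial maps
#' for the retained components, per-component and cumulative explained
#' variance fractions, per-acquisition temporal projections, and the group
#' mean amplitude spectrum per component.
#'
#' @slot eigenvalues all (non-negative) eigenvalues, descending.
#' @slot maps `npix x k` matrix of retained eigenvectors.
#' @slot gridDim `(height, width)` used to reshape maps into images.
#' @slot explained per-component fraction of total variance (all components).
#' @slot nRetained number of retained components (eigenvalue and display caps).
#' @slot temporal list (one per acquisition) of `T x k` projection matrices.
#' @slot spectra list with `freqs` and `amplitude` (`nfreq x k`, group mean).
#' @slot totalVariance sum of all eigenvalues (= trace of the covariance).
#' @export
setClass("PcaModes",
    representation(eigenvalues = "numeric", maps = "matrix",
                   gridDim = "integer", explained = "numeric",
                   nRetained = "integer", temporal = "list",
                   spectra = "list", totalVariance = "numeric"))

setMethod("show", "PcaModes", function(object) {
    k <- object@nRetained
    cum <- sum(object@explained[seq_len(min(10, length(object@explained)))])
    cat(sprintf("PcaModes: %d retained components; 10-component cumulative explained variance %.1f%%\n",
                k, 100 * cum))
})
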