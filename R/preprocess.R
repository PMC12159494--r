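# Temporal preprocessing. The band-pass is a 4th-order Butterworth realised
# as a cascade of second-order high- and low-pass sections (numerically
# stable down to the 0.0008 Hz cut, which on a 20-min record is below
# 1/duration and therefore effectively removes only the mean), applied
# forward-backward (zero phase) with odd-reflection padding. Filtering is
# purely temporal: no spatial mixing.

.designBand <- function(band, dt, nFrames = Inf) {
    ny <- 1 / (2 * dt)
    if (length(band) != 2L || !all(is.finite(band)))
        stop("band must be c(low, high) in Hz")
    if (band[1] < 0 || band[2] <= band[1] || band[2] > ny + 1e-12)
        stop("invalid band [", band[1], ", ", band[2],
             "] Hz for Nyquist ", ny, " Hz")
    # a low cut below the record's fundamental (e.g. 0.0008 Hz on a 20-min
    # record) cannot act as a high-pass on that record; it reduces to exact
    # temporal mean removal, which is also numerically well-behaved
    demean <- FALSE
    if (band[1] > 0 && band[1] <= 1 / (nFrames * dt)) {
        demean <- TRUE
        band[1] <- 0
    }
    filts <- list()
    if (band[1] > 0 && band[2] < ny)
        filts$bp <- signal::butter(2, band / ny, type = "pass")
    else if (band[1] > 0)
        filts$hp <- signal::butter(2, band[1] / ny, type = "high")
    else if (band[2] < ny)
        filts$lp <- signal::butter(2, band[2] / ny, type = "low")
    attr(filts, "demean") <- demean
    filts
}

# zero-phase (forward-backward) gain of the band filter at frequency f
.bandGain <- function(f, band, dt) {
    filts <- .designBand(band, dt)
    g <- rep(1, length(f))
    for (flt in filts) {
        z <- exp(-1i * 2 * pi * f * dt)
        H <- vapply(z, function(zz)
            sum(as.numeric(flt$b) * zz^(seq_along(flt$b) - 1)) /
            sum(as.numeric(flt$a) * zz^(seq_along(flt$a) - 1)), complex(1))
        g <- g * Mod(H)^2               # applied forward and backward
    }
    g
}

# steady-state filter state for unit step input (direct form II transposed),
# so filtering starts transient-free from the padded end values
.lfilterZi <- function(b, a) {
    n <- max(length(a), length(b))
    a <- c(a, rep(0, n - length(a)))
    b <- c(b, rep(0, n - length(b)))
    b <- b / a[1]; a <- a / a[1]
    A <- rbind(-a[2:n], cbind(diag(1, n - 2L), rep(0, n - 2L)))
    B <- b[2:n] - a[2:n] * b[1]
    solve(diag(1, n - 1L) - t(A), B)
}

# zero-phase filtering of the columns of X (time in rows)
.filtfiltMat <- function(X, filts) {
    if (isTRUE(attr(filts, "demean")))
        X <- X - rep(colMeans(X), each = nrow(X))
    for (f in filts) {
        b <- as.numeric(f$b); a <- as.numeric(f$a)
        npad <- min(nrow(X) - 1L, 3L * (max(length(b), length(a)) - 1L))
        X <- cpp_filtfilt_mat(b, a, X, npad, .lfilterZi(b, a))
    }
    X
}

#' Temporal band-pass filter of a movie
#'
#' Applies the zero-phase Butterworth band-pass pixelwise. With a positive
#' low cut the output of every pixel has (near-)zero mean. The resting-state
#' wide band is 0.0008-0.2 Hz and the vasomotor wave band 0.08-0.15 Hz.
#'
#' @param movie a [FusMovie-class].
#' @param band numeric `c(low, high)` in Hz, `0 <= low < high <= Nyquist`.
#' @return A filtered [FusMovie-class] (values may be negative).
#' @export
bandpassMovie <- function(movie, band) {
    spec <- movie@spec
    filts <- .designBand(band, spec@dt, spec@nFrames)
    if (!length(filts) && !isTRUE(attr(filts, "demean"))) return(movie)
    P <- spec@height * spec@width
    X <- movie@data
    dim(X) <- c(P, spec@nFrames)
    X <- t(.filtfiltMat(t(X), filts))
    dim(X) <- c(spec@height, spec@width, spec@nFrames)
    fusMovie(X, spec)
}

#' Band-pass filter one or more time series
#'
#' Same filter as [bandpassMovie()] for plain series (columns of a matrix).
#'
#' @param x numeric vector or `T x n` matrix.
#' @param band `c(low, high)` in Hz.
#' @param dt sampling period in seconds.
#' @return filtered vector/matrix of the same shape.
#' @export
bandpassSeries <- function(x, band, dt) {
    vec <- is.null(dim(x))
    X <- if (vec) matrix(x, ncol = 1L) else x
    filts <- .designBand(band, dt, nrow(X))
    if (!length(filts) && !isTRUE(attr(filts, "demean"))) return(x)
    out <- .filtfiltMat(X, filts)
    if (vec) drop(out) else out
}

#' Relative CBV change, percent
#'
#' `100 * (data - baseline) / baseline` per pixel, where the baseline is the
#' pixel's whole-series mean or its mean over a frame range (e.g. a 30-s
#' pre-stimulation rest).
#'
#' @param movie a [FusMovie-class] of raw intensities.
#' @param baseline `"mean"` or an integer frame range `c(from, to)`.
#' @return A [FusMovie-class] of percent changes.
#' @export
percentChange <- function(movie, baseline = "mean") {
    spec <- movie@spec
    P <- spec@height * spec@width
    X <- movie@data
    dim(X) <- c(P, spec@nFrames)
    b <- if (identical(baseline, "mean")) rowMeans(X)
         else {
             fr <- as.integer(baseline)
             if (length(fr) != 2L || fr[1] < 1L || fr[2] > spec@nFrames ||
                 fr[1] > fr[2])
                 stop("baseline frame range out of bounds")
             rowMeans(X[, fr[1]:fr[2], drop = FALSE])
         }
    bad <- which(b <= 0)
    if (length(bad)) {
        rc <- arrayInd(bad[1], c(spec@height, spec@width))
        stop("non-positive baseline at pixel (row ", rc[1], ", col ", rc[2],
             ")", if (length(bad) > 1) paste0(" and ", length(bad) - 1,
                                             " other pixels"))
    }
    X <- 100 * (X / b - 1)
    dim(X) <- c(spec@height, spec@width, spec@nFrames)
    fusMovie(X, spec)
}

#' Mean time course per region of interest
#'
#' Per-frame unweighted mean of the movie over each ROI's pixels.
#'
#' @param movie a [FusMovie-class].
#' @param atlas a [RoiAtlas-class] on the same grid.
#' @param ids label ids to extract (default: all atlas regions).
#' @return data.frame with `frame`, `time_s` and one column per ROI named
#'   `<Region>_<L|R>`; attributes `ids` and `dt` carry the metadata.
#' @export
roiTimecourses <- function(movie, atlas, ids = roiIds(atlas)) {
    spec <- movie@spec
    if (!identical(dim(atlas@labels), c(spec@height, spec@width)))
        stop("atlas grid does not match the movie")
    lab <- as.integer(atlas@labels)
    X <- movie@data
    dim(X) <- c(spec@height * spec@width, spec@nFrames)
    out <- data.frame(frame = seq_len(spec@nFrames),
                      time_s = (seq_len(spec@nFrames) - 1) * spec@dt)
    for (id in ids) {
        idx <- which(lab == id)
        if (!length(idx)) stop("empty ROI: id ", id)
        nm <- atlas@regionNames[[as.character(id)]]
        hemi <- toupper(substr(atlas@hemispheres[[as.character(id)]], 1, 1))
        col <- if (length(idx) == 1L) X[idx, ] else colMeans(X[idx, , drop = FALSE])
        out[[paste0(nm, "_", hemi)]] <- col
    }
    attr(out, "ids") <- ids
    attr(out, "dt") <- spec@dt
    out
}

#' Earliest longest artifact-free window of a time series
#'
#' Movement artifacts appear as large positive excursions of the Power
#' Doppler time course. A sample is a spike when it exceeds
#' `median + spikeThreshold * 1.4826 * MAD`; the function returns the
#' earliest maximal-length contiguous spike-free window of at least
#' `minDurationS` seconds.
#'
#' @param series numeric time course.
#' @param dt sampling period (s).
#' @param spikeThreshold threshold in robust sd units (default 5).
#' @param minDurationS minimum window length in seconds (default 120).
#' @return integer `c(start, end)` frame indices (1-based, inclusive).
#' @export
artifactFreeWindow <- function(series, dt, spikeThreshold = 5,
                               minDurationS = 120) {
    minFrames <- ceiling(minDurationS / dt)
    if (length(series) < minFrames)
        stop("series shorter than the minimum window (", minDurationS, " s)")
    med <- median(series)
    sdR <- 1.4826 * median(abs(series - med))
    clean <- series <= med + spikeThreshold * sdR
    r <- rle(clean)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= minFrames)
    if (!length(ok))
        stop("no artifact-free window of at least ", minDurationS, " s found")
    best <- ok[which.max(r$lengths[ok])]     # which.max: earliest on ties
    c(start = starts[best], end = ends[best])
}
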