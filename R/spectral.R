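# Amplitude spectra and fractional band amplitude (fALFF). The spectrum is
# the plain one-sided DFT amplitude (no tapering or Welch averaging),
# scaled so a unit sinusoid at an exact bin frequency has amplitude 1:
# amplitude_k = 2 |X_k| / N for 0 < k < N/2 (|X_k| / N at the Nyquist bin),
# DC excluded. Summing amplitude^2 * N / 4 over bins recovers the series'
# energy (Parseval) for in-bin components.

.detrendMat <- function(X) {
    # remove per-column linear trend (least squares)
    n <- nrow(X)
    t1 <- seq_len(n) - (n + 1) / 2
    stt <- sum(t1^2)
    mu <- colMeans(X)
    beta <- as.numeric(crossprod(t1, X)) / stt
    X - rep(mu, each = n) - outer(t1, beta)
}

.amplitudeMat <- function(X, dt, detrend = TRUE) {
    n <- nrow(X)
    if (n < 16L) stop("series too short for a spectrum (need >= 16 samples)")
    if (detrend) X <- .detrendMat(X)
    F <- mvfft(X)
    half <- n %/% 2L
    k <- seq_len(half)
    amp <- 2 * Mod(F[k + 1L, , drop = FALSE]) / n
    if (n %% 2L == 0L) amp[half, ] <- amp[half, ] / 2
    list(freqs = k / (n * dt), amplitude = amp)
}

#' One-sided amplitude spectrum of a time series
#'
#' @param series numeric time course (finite values).
#' @param dt sampling period in seconds.
#' @param detrend remove a linear trend before the transform (default TRUE).
#' @return data.frame with `freq` (Hz, first positive bin to Nyquist) and
#'   `amplitude`.
#' @export
amplitudeSpectrum <- function(series, dt, detrend = TRUE) {
    if (!all(is.finite(series))) stop("series contains non-finite samples")
    sp <- .amplitudeMat(matrix(series, ncol = 1L), dt, detrend)
    data.frame(freq = sp$freqs, amplitude = sp$amplitude[, 1])
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Amplitude summed over the band of interest divided by the amplitude
#' summed over the entire positive-frequency range (DC excluded); always in
#' `[0, 1]`. The default band is the vasomotor 0.08-0.15 Hz. Following the
#' REST-toolbox lineage the ratio uses amplitudes; set `power = TRUE` for a
#' squared-amplitude (power) ratio.
#'
#' @param series numeric time course.
#' @param dt sampling period (s).
#' @param band `c(low, high)` in Hz within `(0, Nyquist]`.
#' @param detrend remove a linear trend first (default TRUE).
#' @param power use squared amplitudes (default FALSE).
#' @return scalar fraction in `[0, 1]`.
#' @export
falff <- function(series, dt, band = c(0.08, 0.15), detrend = TRUE,
                  power = FALSE) {
    sp <- amplitudeSpectrum(series, dt, detrend)
    .falffFromAmp(sp$amplitude, sp$freq, band, power)
}

.falffFromAmp <- function(amp, freqs, band, power = FALSE) {
    inband <- freqs >= band[1] & freqs <= band[2]
    if (!any(inband))
        stop("no frequency bins inside band [", band[1], ", ", band[2], "] Hz")
    if (power) amp <- amp^2
    tot <- sum(amp)
    if (tot <= 0) return(0)
    sum(amp[inband]) / tot
}

#' Pixelwise and per-ROI fALFF maps
#'
#' Computes fALFF per pixel on the raw (unfiltered) movie, per ROI on the
#' ROI-mean series (extraction before analysis), and a thresholded mask of
#' the per-pixel map.
#'
#' @param movie a raw (unfiltered) [FusMovie-class].
#' @param atlas optional [RoiAtlas-class] for the per-ROI table.
#' @param band `c(low, high)` in Hz (default vasomotor 0.08-0.15).
#' @param threshold mask cut on the per-pixel map (default 0.075).
#' @param detrend,power as in [falff()].
#' @return list with `map` (matrix), `roi` (data.frame `roi`, `id`,
#'   `falff`; `NULL` without atlas) and `mask` (logical matrix,
#'   `map > threshold`).
#' @export
falffMap <- function(movie, atlas = NULL, band = c(0.08, 0.15),
                     threshold = 0.075, detrend = TRUE, power = FALSE) {
    spec <- movie@spec
    P <- spec@height * spec@width
    X <- movie@data
    dim(X) <- c(P, spec@nFrames)
    vals <- numeric(P)
    chunk <- 4096L
    for (s in seq.int(1L, P, by = chunk)) {
        e <- min(P, s + chunk - 1L)
        sp <- .amplitudeMat(t(X[s:e, , drop = FALSE]), spec@dt, detrend)
        amp <- sp$amplitude
        if (power) amp <- amp^2
        inband <- sp$freqs >= band[1] & sp$freqs <= band[2]
        if (!any(inband))
            stop("no frequency bins inside band [", band[1], ", ",
                 band[2], "] Hz")
        tot <- colSums(amp)
        vals[s:e] <- ifelse(tot > 0, colSums(amp[inband, , drop = FALSE]) / tot, 0)
    }
    map <- matrix(vals, spec@height, spec@width)
    roi <- NULL
    if (!is.null(atlas)) {
        tc <- roiTimecourses(movie, atlas)
        ids <- attr(tc, "ids")
        nmcols <- setdiff(names(tc), c("frame", "time_s"))
        roi <- data.frame(roi = nmcols, id = ids,
                          falff = vapply(nmcols, function(nm)
                              falff(tc[[nm]], spec@dt, band, detrend, power),
                              numeric(1)),
                          row.names = NULL)
    }
    list(map = map, roi = roi, mask = map > threshold)
}
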