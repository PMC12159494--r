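# Group-mean-covariance PCA ("oscillatory modes"). Each acquisition is
# band-pass filtered, centred by its global (all-pixel, all-frame) mean and
# divided by its global sd — one scalar per acquisition, preserving the
# relative spatial amplitude structure — then flattened to pixel x time.
# The pixelwise covariance matrices are averaged over the group's
# acquisitions and eigen-decomposed; when the stacked frame count is
# smaller than the pixel count the decomposition runs on the time x time
# Gram matrix (identical non-zero spectrum).

#' Preprocess movies for the covariance PCA
#'
#' Band-pass, subtract the global mean, divide by the global sd, and
#' reshape each acquisition to a `pixel x time` matrix.
#'
#' @param movies list of [FusMovie-class] sharing one grid.
#' @param band `c(low, high)` in Hz (default wide 0.0008-0.2 band).
#' @return list of `P x T` matrices with attribute `gridDim`.
#' @export
preprocessForPca <- function(movies, band = c(0.0008, 0.2)) {
    if (!length(movies)) stop("need at least one movie")
    d0 <- dim(movies[[1]]@data)[1:2]
    out <- vector("list", length(movies))
    for (i in seq_along(movies)) {
        m <- movies[[i]]
        if (!identical(dim(m@data)[1:2], d0))
            stop("movies must share one grid shape")
        f <- bandpassMovie(m, band)
        X <- f@data
        dim(X) <- c(d0[1] * d0[2], dim(f@data)[3])
        mu <- mean(X)
        sdg <- sd(as.numeric(X))
        if (sdg == 0)
            stop("degenerate acquisition ", i, ": zero global sd after filtering")
        out[[i]] <- (X - mu) / sdg
    }
    attr(out, "gridDim") <- as.integer(d0)
    out
}

#' Mean spatial covariance of a group of preprocessed acquisitions
#'
#' Mean over acquisitions of the `pixel x pixel` covariance computed across
#' time (`X X' / (T - 1)`; the data are already globally centred).
#' Symmetric positive semidefinite up to round-off.
#'
#' @param preprocessed list from [preprocessForPca()].
#' @return `P x P` covariance matrix.
#' @export
groupMeanCovariance <- function(preprocessed) {
    if (!length(preprocessed)) stop("need at least one acquisition")
    P <- nrow(preprocessed[[1]])
    if (P > 8192L)
        stop("covariance would be ", P, " x ", P,
             " pixels; use a coarser grid for direct covariance PCA")
    acc <- matrix(0, P, P)
    for (X in preprocessed) {
        T <- ncol(X)
        if (T < 2L) stop("single-frame acquisition: covariance undefined")
        acc <- acc + tcrossprod(X) / (T - 1)
    }
    acc / length(preprocessed)
}

.orientModes <- function(V) {
    # deterministic polarity: largest-|.| element of each eigenvector positive
    for (k in seq_len(ncol(V))) {
        j <- which.max(abs(V[, k]))
        if (V[j, k] < 0) V[, k] <- -V[, k]
    }
    V
}

#' Eigenmodes of a (group-mean) covariance matrix
#'
#' Full symmetric eigen-decomposition; eigenvalues sorted descending.
#' Components with eigenvalue above `eigenvalueMin` are retained, capped at
#' `nDisplay`. The explained fraction of each component is its eigenvalue
#' over the eigenvalue sum (= trace).
#'
#' @param cov symmetric covariance matrix.
#' @param eigenvalueMin retention threshold (default 0.1, on the covariance
#'   of globally sd-normalised data).
#' @param nDisplay cap on retained components (default 10).
#' @param gridDim `(height, width)` for reshaping eigenvectors into maps.
#' @return A [PcaModes-class] (temporal/spectral slots empty; see
#'   [projectModes()]).
#' @export
eigenModes <- function(cov, eigenvalueMin = 0.1, nDisplay = 10L,
                       gridDim = NULL) {
    if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-7)))
        stop("covariance matrix must be symmetric")
    e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    keep <- which(ev > eigenvalueMin)
    k <- min(length(keep), as.integer(nDisplay))
    tot <- sum(ev)
    if (is.null(gridDim)) gridDim <- c(nrow(cov), 1L)
    new("PcaModes",
        eigenvalues = ev,
        maps = .orientModes(e$vectors[, seq_len(k), drop = FALSE]),
        gridDim = as.integer(gridDim),
        explained = if (tot > 0) ev / tot else ev,
        nRetained = as.integer(k),
        temporal = list(), spectra = list(),
        totalVariance = tot)
}

# eigen-decomposition via the stacked time x time Gram matrix (used when
# total frames < pixels); returns the same non-zero spectrum and maps
.eigenModesGram <- function(preprocessed, eigenvalueMin, nDisplay, gridDim) {
    g <- length(preprocessed)
    Ts <- vapply(preprocessed, ncol, 1L)
    M <- do.call(cbind, lapply(preprocessed,
                               function(X) X / sqrt(g * (ncol(X) - 1))))
    G <- crossprod(M)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    P <- nrow(M)
    evFull <- c(ev, rep(0, max(0L, P - length(ev))))
    keep <- which(evFull > eigenvalueMin)
    k <- min(length(keep), as.integer(nDisplay))
    V <- M %*% e$vectors[, seq_len(k), drop = FALSE]
    V <- sweep(V, 2, sqrt(ev[seq_len(k)]), "/")
    tot <- sum(evFull)
    new("PcaModes",
        eigenvalues = evFull,
        maps = .orientModes(V),
        gridDim = as.integer(gridDim),
        explained = if (tot > 0) evFull / tot else evFull,
        nRetained = as.integer(k),
        temporal = list(), spectra = list(),
        totalVariance = tot)
}

#' Temporal projections and mode spectra
#'
#' Projects each acquisition onto the retained eigenvectors
#' (`projection_k(t) = eigenvector_k . frame_t`) and averages the one-sided
#' amplitude spectra of the projections across acquisitions.
#'
#' @param preprocessed list from [preprocessForPca()].
#' @param modes a [PcaModes-class].
#' @param dt frame period in seconds.
#' @return `modes` with `temporal` (list of `T x k` matrices) and `spectra`
#'   (`freqs`, `amplitude` `nfreq x k` group mean) filled in.
#' @export
projectModes <- function(preprocessed, modes, dt) {
    k <- modes@nRetained
    if (!k) stop("no retained components to project on")
    if (nrow(preprocessed[[1]]) != nrow(modes@maps))
        stop("pixel dimension mismatch between data and modes")
    proj <- lapply(preprocessed, function(X) crossprod(X, modes@maps))
    spec1 <- .amplitudeMat(proj[[1]], dt, detrend = TRUE)
    accum <- spec1$amplitude
    if (length(proj) > 1L)
        for (i in 2:length(proj))
            accum <- accum + .amplitudeMat(proj[[i]], dt, detrend = TRUE)$amplitude
    modes@temporal <- proj
    modes@spectra <- list(freqs = spec1$freqs,
                          amplitude = accum / length(proj))
    modes
}

#' Full group PCA driver
#'
#' Convenience wrapper: preprocess, mean covariance (direct, or via the
#' time x time Gram duality when the stacked frame count is below the pixel
#' count), eigenmodes, projections and spectra.
#'
#' @param movies list of [FusMovie-class].
#' @param band,eigenvalueMin,nDisplay see [preprocessForPca()] and
#'   [eigenModes()].
#' @return A [PcaModes-class] with temporal projections and spectra.
#' @export
pcaModes <- function(movies, band = c(0.0008, 0.2), eigenvalueMin = 0.1,
                     nDisplay = 10L) {
    pre <- preprocessForPca(movies, band)
    gridDim <- attr(pre, "gridDim")
    P <- nrow(pre[[1]])
    totT <- sum(vapply(pre, ncol, 1L))
    modes <- if (totT < P)
        .eigenModesGram(pre, eigenvalueMin, nDisplay, gridDim)
    else
        eigenModes(groupMeanCovariance(pre), eigenvalueMin, nDisplay, gridDim)
    projectModes(pre, modes, dt = movies[[1]]@spec@dt)
}

#' Reconstruct an acquisition from its first k modes
#'
#' `sum_{i<=k} map_i * projection_i(t)`, reshaped to the movie grid, with
#' the residual variance fraction of the reconstruction.
#'
#' @param preprocessedAcq one `P x T` matrix from [preprocessForPca()].
#' @param modes a [PcaModes-class].
#' @param k number of components (0 gives an all-zero reconstruction).
#' @return list with `reconstruction` (`height x width x T` array) and
#'   `residualFraction`.
#' @export
reconstructFromModes <- function(preprocessedAcq, modes, k) {
    if (k > modes@nRetained)
        stop("k = ", k, " exceeds the ", modes@nRetained,
             " retained components")
    P <- nrow(preprocessedAcq); T <- ncol(preprocessedAcq)
    recon <- if (k == 0L) matrix(0, P, T) else {
        V <- modes@maps[, seq_len(k), drop = FALSE]
        V %*% crossprod(V, preprocessedAcq)
    }
    resid <- preprocessedAcq - recon
    tot <- sum(preprocessedAcq^2)
    rf <- if (tot > 0) sum(resid^2) / tot else 0
    dim(recon) <- c(modes@gridDim[1], modes@gridDim[2], T)
    list(reconstruction = recon, residualFraction = rf)
}
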