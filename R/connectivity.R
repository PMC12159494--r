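# Static ROI-ROI functional connectivity (Pearson r with Fisher z) and
# sliding-window dynamic seed-based connectivity. Series are expected to be
# band-pass filtered upstream (wide 0.0008-0.2 Hz band for static FC,
# vasomotor 0.08-0.15 Hz band for the dynamic seed analysis).

.tcMatrix <- function(timecourses) {
    if (is.data.frame(timecourses)) {
        cols <- setdiff(names(timecourses), c("frame", "time_s"))
        as.matrix(timecourses[cols])
    } else as.matrix(timecourses)
}

#' Static functional connectivity matrix
#'
#' Pearson correlation between all pairs of ROI time courses, plus the
#' Fisher z transform (`atanh` of r clipped to +/-(1 - 1e-7)).
#'
#' @param timecourses data.frame from [roiTimecourses()] (or a plain
#'   `T x nROI` matrix with column names).
#' @return An [FcMatrix-class].
#' @export
staticFC <- function(timecourses) {
    M <- .tcMatrix(timecourses)
    sds <- apply(M, 2, sd)
    if (any(sds == 0))
        stop("zero-variance series for ROI ",
             paste(colnames(M)[sds == 0], collapse = ", "))
    r <- cor(M)
    rc <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(rc)
    diag(z) <- 0
    new("FcMatrix", roiIds = colnames(M), r = r, z = z)
}

#' Group difference of functional connectivity
#'
#' Element-wise `mean(z_a) - mean(z_b)` of the Fisher-transformed matrices,
#' reported both on the z scale and back-transformed to correlation units
#' (`tanh(mean z_a) - tanh(mean z_b)`).
#'
#' @param groupA,groupB lists of [FcMatrix-class] over the same ROIs.
#' @return list with `deltaZ`, `deltaR` and `roiIds`.
#' @export
fcDifference <- function(groupA, groupB) {
    if (!length(groupA) || !length(groupB))
        stop("each group needs at least one FC matrix")
    ids <- groupA[[1]]@roiIds
    all_ <- c(groupA, groupB)
    if (!all(vapply(all_, function(m) identical(m@roiIds, ids), TRUE)))
        stop("ROI sets differ between matrices")
    mz <- function(g) Reduce(`+`, lapply(g, fcZ)) / length(g)
    za <- mz(groupA); zb <- mz(groupB)
    list(deltaZ = za - zb, deltaR = tanh(za) - tanh(zb), roiIds = ids)
}

#' Sliding-window dynamic seed-based connectivity
#'
#' Per window of `windowFrames` successive frames (default 15, i.e. 6 s at
#' dt = 0.4 s) advancing by `step` frames, the Pearson correlation between
#' the seed-ROI mean time course and every pixel is computed; the trace is
#' the mean correlation over the target ROI's pixels, stamped at the window
#' centre.
#'
#' @param movie a [FusMovie-class], band-pass filtered to the wave band
#'   upstream.
#' @param atlas a [RoiAtlas-class].
#' @param seedRoi,targetRoi atlas label id vectors (see [lookupRoi()]).
#' @param windowFrames window length in frames (>= 3).
#' @param step window step in frames.
#' @param aggregate `"r"` (mean correlation, default) or `"z"` (mean Fisher
#'   z, back-transformed).
#' @return data.frame with `time_s` and `r`; attribute `window_s` gives the
#'   window length in seconds.
#' @export
dynamicSeedFC <- function(movie, atlas, seedRoi, targetRoi,
                          windowFrames = 15L, step = 1L, aggregate = "r") {
    spec <- movie@spec
    w <- as.integer(windowFrames)
    if (w < 3L) stop("windowFrames must be >= 3")
    if (w > spec@nFrames) stop("window longer than the record")
    lab <- as.integer(atlas@labels)
    X <- movie@data
    dim(X) <- c(spec@height * spec@width, spec@nFrames)
    seedIdx <- which(lab %in% seedRoi)
    tgtIdx <- which(lab %in% targetRoi)
    if (!length(seedIdx)) stop("empty seed ROI")
    if (!length(tgtIdx)) stop("empty target ROI")
    s <- if (length(seedIdx) == 1L) X[seedIdx, ]
         else colMeans(X[seedIdx, , drop = FALSE])
    Y <- t(X[tgtIdx, , drop = FALSE])              # T x nTarget
    starts <- seq.int(1L, spec@nFrames - w + 1L, by = as.integer(step))
    # windowed sums via cumulative sums
    cs1 <- function(v) { c0 <- cumsum(v); c0[starts + w - 1L] -
            c(0, c0)[starts] }
    csM <- function(M) { C <- apply(M, 2, cumsum)
        C[starts + w - 1L, , drop = FALSE] -
            rbind(0, C)[starts, , drop = FALSE] }
    Ss <- cs1(s); Sss <- cs1(s * s)
    Sy <- csM(Y); Syy <- csM(Y * Y); Ssy <- csM(Y * s)
    vs <- Sss - Ss^2 / w
    vy <- Syy - Sy^2 / w
    cov <- Ssy - outer(Ss, rep(1, ncol(Y))) * Sy / w
    den <- sqrt(pmax(vs, 0)) * sqrt(pmax(vy, 0))
    r <- cov / den
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -1), 1)
    val <- if (identical(aggregate, "z")) {
        tanh(rowMeans(atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))))
    } else rowMeans(r)
    out <- data.frame(time_s = (starts - 1 + (w - 1) / 2) * spec@dt, r = val)
    attr(out, "window_s") <- w * spec@dt
    out
}
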