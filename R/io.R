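# Movie and atlas IO. Two containers are supported: multi-page TIFF (one
# 32-bit float page per frame, intensities stored normalised with the scale
# recorded in a sidecar JSON together with dt and pixel size) and NIfTI-1
# (x, y, t array; pixdim carries pixel_mm, pixel_mm, dt so no sidecar is
# needed). All writers log the originating seed when one is supplied.

.sidecarPath <- function(path) paste0(sub("\\.(tiff?|nii(\\.gz)?)$", "", path),
                                      ".json")

.isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Write a CBV movie to disk
#'
#' @param movie a [FusMovie-class].
#' @param path output file: `.tif`/`.tiff` (multi-page float TIFF plus a
#'   sidecar JSON with `dt_s`, `pixel_mm` and the intensity scale) or
#'   `.nii`/`.nii.gz` (float NIfTI with `pixdim = (pixel_mm, pixel_mm, dt)`).
#' @param seed optional integer recorded in the sidecar/description for
#'   provenance.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path, seed = NULL) {
    spec <- movie@spec
    if (.isTiff(path)) {
        scale <- max(movie@data)
        if (scale <= 0) scale <- 1
        pages <- lapply(seq_len(spec@nFrames),
                        function(t) movie@data[, , t] / scale)
        tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                        compression = "none", reduce = FALSE)
        meta <- list(dt_s = spec@dt, pixel_mm = spec@pixelMm,
                     intensity_scale = scale,
                     n_frames = spec@nFrames, seed = seed)
        jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                             digits = NA)
    } else if (.isNifti(path)) {
        img <- RNifti::asNifti(movie@data)
        RNifti::pixdim(img) <- c(spec@pixelMm, spec@pixelMm, spec@dt)
        RNifti::writeNifti(img, path, datatype = "float")
    } else stop("unsupported movie format: ", path,
                " (use .tif/.tiff or .nii/.nii.gz)")
    invisible(path)
}

#' Read a CBV movie from disk
#'
#' Round-trips [writeMovie()] output: values are recovered to 32-bit float
#' precision and the acquisition metadata (`dt`, pixel size) is restored
#' from the sidecar JSON (TIFF) or the NIfTI header.
#'
#' @param path movie file written by [writeMovie()].
#' @param dt,pixelMm fallbacks when no metadata is found.
#' @return A [FusMovie-class].
#' @export
readMovie <- function(path, dt = 0.4, pixelMm = 0.1) {
    if (.isTiff(path)) {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
        if (!length(pages)) stop("format error: TIFF contains no pages")
        dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
        if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
            stop("format error: TIFF pages have inconsistent shapes")
        scale <- 1
        sc <- .sidecarPath(path)
        if (file.exists(sc)) {
            meta <- jsonlite::read_json(sc)
            dt <- meta$dt_s %||% dt
            pixelMm <- meta$pixel_mm %||% pixelMm
            scale <- meta$intensity_scale %||% 1
        }
        data <- array(unlist(pages), dim = c(dims[1, 1], dims[2, 1],
                                             length(pages))) * scale
        fusMovie(data, dt = dt, pixelMm = pixelMm)
    } else if (.isNifti(path)) {
        img <- RNifti::readNifti(path)
        pd <- RNifti::pixdim(img)
        data <- array(as.numeric(img), dim = dim(img))
        if (length(pd) >= 3 && pd[3] > 0) dt <- pd[3]
        if (length(pd) >= 1 && pd[1] > 0) pixelMm <- pd[1]
        fusMovie(data, dt = dt, pixelMm = pixelMm)
    } else stop("unsupported movie format: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ROI atlas (integer label map plus JSON name table)
#'
#' @param atlas a [RoiAtlas-class].
#' @param path `.nii`/`.nii.gz` or `.tif` label image; region names and
#'   hemispheres go to the sidecar JSON.
#' @param seed optional provenance seed for the sidecar.
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path, seed = NULL) {
    lab <- atlas@labels
    if (.isTiff(path)) {
        tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L,
                        compression = "none")
    } else if (.isNifti(path)) {
        RNifti::writeNifti(RNifti::asNifti(lab), path, datatype = "int16")
    } else stop("unsupported atlas format: ", path)
    meta <- list(names = as.list(atlas@regionNames),
                 hemispheres = as.list(atlas@hemispheres), seed = seed)
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE)
    invisible(path)
}

#' Read an ROI atlas written by [writeAtlas()]
#'
#' @param path atlas label image with its sidecar JSON next to it.
#' @return A [RoiAtlas-class].
#' @export
readAtlas <- function(path) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) stop("atlas sidecar JSON not found: ", sc)
    meta <- jsonlite::read_json(sc)
    lab <- if (.isTiff(path)) {
        round(tiff::readTIFF(path, as.is = FALSE) * 255)
    } else if (.isNifti(path)) {
        img <- RNifti::readNifti(path)
        matrix(as.numeric(img), dim(img)[1], dim(img)[2])
    } else stop("unsupported atlas format: ", path)
    storage.mode(lab) <- "integer"
    new("RoiAtlas", labels = lab,
        regionNames = unlist(meta$names),
        hemispheres = unlist(meta$hemispheres))
}

#' Write the simulator's ground-truth event registry as JSON
#'
#' @param groundTruth a [GroundTruthLog-class].
#' @param path output `.json` file.
#' @param seed optional provenance seed.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path, seed = NULL) {
    ev <- lapply(groundTruth@events, function(e) {
        e$centroidTrack <- if (nrow(e$centroidTrack))
            apply(e$centroidTrack, 1, as.list) else list()
        e
    })
    jsonlite::write_json(list(seed = seed, events = ev), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
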