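# Accessor generics. Slots are never reached into from user code.

#' @name accessors
#' @title Accessors for fuswaves containers
#' @param object a fuswaves S4 object.
#' @param x a fuswaves S4 object.
#' @description Read-only accessors for the S4 containers: movie voxel data
#'   and acquisition constants, atlas label maps and region metadata,
#'   connectivity matrices and PCA mode components.
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setMethod("movieData", "FusMovie", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("movieSpec", function(x) standardGeneric("movieSpec"))
#' @rdname accessors
#' @export
setMethod("movieSpec", "FusMovie", function(x) x@spec)

#' @rdname accessors
#' @export
setGeneric("frameDt", function(x) standardGeneric("frameDt"))
#' @rdname accessors
#' @export
setMethod("frameDt", "AcquisitionSpec", function(x) x@dt)
#' @rdname accessors
#' @export
setMethod("frameDt", "FusMovie", function(x) x@spec@dt)

#' @rdname accessors
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))
#' @rdname accessors
#' @export
setMethod("pixelSizeMm", "AcquisitionSpec", function(x) x@pixelMm)
#' @rdname accessors
#' @export
setMethod("pixelSizeMm", "FusMovie", function(x) x@spec@pixelMm)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "AcquisitionSpec", function(x) x@nFrames)
#' @rdname accessors
#' @export
setMethod("nFrames", "FusMovie", function(x) x@spec@nFrames)

#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setMethod("atlasLabels", "RoiAtlas", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setMethod("roiNames", "RoiAtlas", function(x) x@regionNames)

#' @rdname accessors
#' @export
setGeneric("roiHemispheres", function(x) standardGeneric("roiHemispheres"))
#' @rdname accessors
#' @export
setMethod("roiHemispheres", "RoiAtlas", function(x) x@hemispheres)

#' @rdname accessors
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setMethod("roiIds", "RoiAtlas", function(x) as.integer(names(x@regionNames)))

#' Look up atlas label ids by region name and hemisphere
#'
#' @param atlas a [RoiAtlas-class].
#' @param name region name, e.g. `"PrimVisCtx"`; vectorised.
#' @param hemisphere `"left"`, `"right"` or `"both"`.
#' @return integer vector of label ids.
#' @export
lookupRoi <- function(atlas, name, hemisphere = "both") {
    ids <- names(atlas@regionNames)
    keep <- atlas@regionNames %in% name
    if (hemisphere != "both")
        keep <- keep & atlas@hemispheres[ids] == hemisphere
    out <- as.integer(ids[keep])
    if (!length(out))
        stop("no atlas region named '", paste(name, collapse = ","),
             "' in hemisphere '", hemisphere, "'")
    out
}

#' @rdname accessors
#' @export
setGeneric("fcR", function(x) standardGeneric("fcR"))
#' @rdname accessors
#' @export
setMethod("fcR", "FcMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("fcZ", function(x) standardGeneric("fcZ"))
#' @rdname accessors
#' @export
setMethod("fcZ", "FcMatrix", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("modeEigenvalues", function(x) standardGeneric("modeEigenvalues"))
#' @rdname accessors
#' @export
setMethod("modeEigenvalues", "PcaModes", function(x) x@eigenvalues)

#' Spatial map of one retained principal component, as an image matrix
#'
#' @param modes a [PcaModes-class].
#' @param k component index (1 = largest eigenvalue).
#' @return a `height x width` matrix.
#' @export
modeMap <- function(modes, k) {
    if (k < 1 || k > modes@nRetained)
        stop("component index out of range (", modes@nRetained, " retained)")
    matrix(modes@maps[, k], modes@gridDim[1], modes@gridDim[2])
}

#' Explained variance fractions of a PCA mode decomposition
#'
#' @param modes a [PcaModes-class].
#' @param cumulative if `TRUE`, return the running cumulative fraction.
#' @return numeric vector over all components (not just retained ones).
#' @export
explainedVariance <- function(modes, cumulative = FALSE) {
    if (cumulative) cumsum(modes@explained) else modes@explained
}

#' @rdname accessors
#' @export
setGeneric("eventRecords", function(x) standardGeneric("eventRecords"))
#' @rdname accessors
#' @export
setMethod("eventRecords", "EventSet", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("eventRecords", "GroundTruthLog", function(x) x@events)
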