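# Schematic bilateral ROI atlas. The geometry mimics a coronal imaging plane
# through posterior cortex: a cortical ribbon of five regions per hemisphere
# ordered medial -> temporal, with hippocampal and midbrain territories
# below it. Only the topology (medial/temporal order, cortex above
# subcortex, two mirrored hemispheres) matters for pattern labelling; the
# atlas is not anatomically registered.

.CORTEX_MEDIAL_TO_TEMPORAL <- c("RetroGrCtx_B", "RetroGrCtx_A", "RetroDysCtx",
                                "SecVisCtx", "PrimVisCtx")
.REGION_ORDER <- c("PrimVisCtx", "SecVisCtx", "RetroDysCtx", "RetroGrCtx_A",
                   "RetroGrCtx_B", "SuperiorColl", "Hippocampus",
                   "DorsalMidbrain", "VentralMidbrain")

#' Names of the nine atlas regions
#'
#' @return character vector of the canonical region names, cortical regions
#'   first (lateral to medial), then subcortical territories.
#' @export
regionNamesCanonical <- function() .REGION_ORDER

#' Build the schematic bilateral ROI atlas
#'
#' Lays out the nine named regions on the movie grid: a cortical band near
#' the top split into five medial-to-temporal sectors per hemisphere
#' (RetroGrCtx_B at the midline out to PrimVisCtx), then the superior
#' colliculus (medial) and hippocampus (lateral), the dorsal midbrain, and
#' the ventral midbrain. The map is mirror-symmetric about the vertical
#' midline up to the left/right id swap (left ids 1-9, right ids 11-19).
#'
#' @param spec an [AcquisitionSpec-class]; only `height`/`width` are used.
#' @return A [RoiAtlas-class].
#' @examples
#' atlas <- buildAtlas(acquisitionSpec(128, 128, 100))
#' table(atlasLabels(atlas) > 0)
#' @export
buildAtlas <- function(spec) {
    h <- spec@height; w <- spec@width
    if (h < 64L || w < 64L)
        stop("atlas grid too small: need at least 64 x 64 pixels to place all regions")
    lab <- matrix(0L, h, w)
    wl <- w %/% 2L                       # columns in the left hemisphere
    cmargin <- max(2L, round(0.04 * w))
    rows <- function(a, b) seq.int(max(1L, round(a * h)), min(h, round(b * h)))
    rCortex <- rows(0.08, 0.30)
    rSub1   <- rows(0.33, 0.50)          # hippocampus (lateral) + sup. colliculus (medial)
    rDMid   <- rows(0.53, 0.70)
    rVMid   <- rows(0.73, 0.88)
    usable <- seq.int(cmargin + 1L, wl)  # left-hemisphere columns, lateral -> medial
    nu <- length(usable)

    # cortical ribbon: five equal sectors, medial (near midline) -> temporal
    cuts <- round(seq(0, nu, length.out = 6L))
    baseId <- c(PrimVisCtx = 1L, SecVisCtx = 2L, RetroDysCtx = 3L,
                RetroGrCtx_A = 4L, RetroGrCtx_B = 5L, SuperiorColl = 6L,
                Hippocampus = 7L, DorsalMidbrain = 8L, VentralMidbrain = 9L)
    for (i in seq_len(5L)) {
        nm <- .CORTEX_MEDIAL_TO_TEMPORAL[i]          # i = 1 is most medial
        cols <- usable[seq.int(nu - cuts[i + 1L] + 1L, nu - cuts[i])]
        lab[rCortex, cols] <- baseId[[nm]]
    }
    # subcortical band: medial 40% = superior colliculus, lateral 60% = hippocampus
    nmed <- round(0.4 * nu)
    lab[rSub1, usable[seq.int(nu - nmed + 1L, nu)]] <- baseId[["SuperiorColl"]]
    lab[rSub1, usable[seq_len(nu - nmed)]] <- baseId[["Hippocampus"]]
    lab[rDMid, usable] <- baseId[["DorsalMidbrain"]]
    lab[rVMid, usable] <- baseId[["VentralMidbrain"]]

    # mirror to the right hemisphere with ids offset by 10
    right <- lab[, wl:1L, drop = FALSE]
    right[right > 0L] <- right[right > 0L] + 10L
    lab[, seq.int(w - wl + 1L, w)] <- right

    ids <- c(baseId, baseId + 10L)
    regionNames <- setNames(rep(names(baseId), 2L), as.character(ids))
    hemis <- setNames(rep(c("left", "right"), each = length(baseId)),
                      as.character(ids))
    atlas <- new("RoiAtlas", labels = lab, regionNames = regionNames,
                 hemispheres = hemis)
    counts <- table(lab[lab > 0L])
    if (min(counts) < 15L)
        stop("atlas grid too small: smallest region has fewer than 15 pixels")
    atlas
}

#' Coarse anatomical class of every atlas pixel
#'
#' @param atlas a [RoiAtlas-class].
#' @return integer matrix: 0 background, 1 cortex, 2 hippocampus,
#'   3 other subcortex.
#' @export
regionClassMap <- function(atlas) {
    lab <- atlas@labels
    cls <- matrix(0L, nrow(lab), ncol(lab))
    nm <- atlas@regionNames
    cortexIds <- as.integer(names(nm)[nm %in% .CORTEX_MEDIAL_TO_TEMPORAL])
    hippIds <- as.integer(names(nm)[nm == "Hippocampus"])
    cls[lab %in% cortexIds] <- 1L
    cls[lab %in% hippIds] <- 2L
    cls[lab > 0L & cls == 0L] <- 3L
    cls
}

#' Geometric centroid of an atlas region
#'
#' @param atlas a [RoiAtlas-class].
#' @param id a label id present in the atlas.
#' @return numeric `(row, col)`.
#' @export
roiCentroid <- function(atlas, id) {
    idx <- which(atlas@labels == id, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty ROI: id ", id, " not present in atlas")
    c(mean(idx[, 1]), mean(idx[, 2]))
}
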