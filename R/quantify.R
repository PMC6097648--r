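## Derived measurements on binary masks.  All physical units come from
## the mask geometry: areas in um^2, volumes in um^3.

## Sum of foreground per position along one array axis.
countsAlongAxis <- function(a, axis) {
    apply(a, axis, sum)
}

#' Per-slice foreground area and total volume
#'
#' Area per slice (foreground voxels times dx*dy) along the
#' anteroposterior axis, and the total volume (sum of areas times dz).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return a \linkS4class{SliceProfile}.
#' @export
perSliceArea <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    g <- geometry(mask)
    counts <- countsAlongAxis(maskArray(mask), g@apAxis)
    areas <- counts * g@dx * g@dy
    new("SliceProfile", areas = areas, dz = g@dz,
        totalVolume = sum(areas) * g@dz)
}

#' Overlap (AND) volume of two masks
#'
#' Volume of the voxelwise conjunction, the putative-active-zone and
#' colocalization measure: Brp AND GF gives AZ apposed to the GF
#' dendrite, ShB AND Brp the gap-junction/active-zone colocalization.
#'
#' @param a,b congruent \linkS4class{BinaryMask} objects.
#' @return overlap volume, um^3.
#' @export
overlapVolume <- function(a, b) {
    stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
    stopIfIncongruent(a, b, "overlap masks")
    sum(maskArray(a) & maskArray(b)) * voxelVolumeUm3(geometry(a))
}

#' Single-pixel-outline surface-area proxy
#'
#' Estimates the surface area of a binary structure as the voxel volume
#' of its one-pixel outline ([outline1px()]) divided by the in-plane
#' pixel size dx: the outline shell is one pixel thick, so its volume
#' over its thickness approximates the bounding surface.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return surface-area estimate, um^2.
#' @examples
#' g <- voxelGeometry()            # 0.22 um pixels, 1 um slices
#' a <- array(FALSE, c(5, 5, 1)); a[3, 3, 1] <- TRUE
#' surfaceAreaProxy(binaryMask(a, g))   # 0.22^2 * 1 / 0.22 = 0.22 um^2
#' @export
surfaceAreaProxy <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    maskVolume(outline1px(mask)) / geometry(mask)@dx
}

#' Partition a dendrite mask at a medial boundary
#'
#' Splits the GF dendrite mask into the medially-projecting part and
#' the core: the mediolateral centre is the centroid (on the
#' mediolateral axis) of the largest 6-connected component, the
#' boundary plane lies \code{boundaryUm} medial of it (pixel offset =
#' round(boundary / dx), which is 23 pixels for 5 um at 0.22 um), and
#' voxels strictly beyond the plane in the medial direction are medial.
#' The two outputs are disjoint and together reproduce the input.
#'
#' @param gfMask nonempty \linkS4class{BinaryMask} of the GF dendrite.
#' @param boundaryUm boundary distance medial of the centre, um
#'   (default 5).
#' @return list with elements \code{medial} and \code{core}
#'   (\linkS4class{BinaryMask}) plus \code{centerIndex} and
#'   \code{offsetPixels}.
#' @export
partitionMedial <- function(gfMask, boundaryUm = 5) {
    stopifnot(is(gfMask, "BinaryMask"))
    a <- maskArray(gfMask)
    if (!any(a)) stop("empty GF mask", call. = FALSE)
    g <- geometry(gfMask)
    ml <- mlAxisFor(g@apAxis)
    lab <- array(cpp_label3d(a, dim(a)), dim(a))
    largest <- which.max(tabulate(lab[lab > 0L]))
    comp <- lab == largest
    mlIndex <- slice.index(a, ml)
    center <- roundHalfUp(mean(mlIndex[comp]))
    offsetPx <- roundHalfUp(boundaryUm / g@dx)
    beyond <- (mlIndex - center) * g@medialDirection > offsetPx
    medial <- a & beyond
    core <- a & !beyond
    list(medial = binaryMask(medial, g), core = binaryMask(core, g),
         centerIndex = center, offsetPixels = offsetPx)
}

#' Neurobiotin dye-coupling cross-sectional area
#'
#' Mean cross-sectional NB foreground area over a window of slices
#' centred on the anteriormost tip of the GF dendrite (the first slice
#' along the anterior direction with any GF foreground; ties cannot
#' occur since the first such slice is unique).  The window spans
#' round(windowLength / dz) slices and is clamped to the stack.
#'
#' @param nbMask \linkS4class{BinaryMask} of the NB channel.
#' @param gfMask congruent nonempty \linkS4class{BinaryMask} of the GF.
#' @param windowLengthUm window length along the AP axis, um
#'   (default 10, i.e. ten 1-um slices).
#' @return mean NB area over the window, um^2.
#' @export
nbCouplingArea <- function(nbMask, gfMask, windowLengthUm = 10) {
    stopifnot(is(nbMask, "BinaryMask"), is(gfMask, "BinaryMask"))
    stopIfIncongruent(nbMask, gfMask, "NB and GF masks")
    g <- geometry(gfMask)
    gfPerSlice <- countsAlongAxis(maskArray(gfMask), g@apAxis)
    if (!any(gfPerSlice > 0)) stop("empty GF mask", call. = FALSE)
    tip <- which(gfPerSlice > 0)[1L]   # anterior = lowest slice index
    nWin <- max(1L, roundHalfUp(windowLengthUm / g@dz))
    from <- max(1L, tip - floor(nWin / 2))
    to <- min(length(gfPerSlice), from + nWin - 1L)
    nbPerSlice <- countsAlongAxis(maskArray(nbMask), g@apAxis)
    mean(nbPerSlice[from:to]) * g@dx * g@dy
}

#' Per-region ShakB/Brp colocalization
#'
#' For each named region mask (for example the JO-A and JO-B axon
#' territories): the ShakB volume inside the region, the volume of
#' ShakB AND Brp inside the region, and the percentage of ShakB
#' colocalized with Brp (0 when the region holds no ShakB, with a
#' warning).
#'
#' @param shbMask \linkS4class{BinaryMask} of the ShakB channel.
#' @param brpMask congruent \linkS4class{BinaryMask} of the Brp channel.
#' @param regions named list of congruent region
#'   \linkS4class{BinaryMask}s.
#' @return data.frame with columns region, shbVolume, overlapVolume,
#'   percentColocalized.
#' @export
colocalization <- function(shbMask, brpMask, regions) {
    stopifnot(is(shbMask, "BinaryMask"), is(brpMask, "BinaryMask"),
              is.list(regions), length(regions) > 0L,
              !is.null(names(regions)))
    stopIfIncongruent(shbMask, brpMask, "ShB and Brp masks")
    vox <- voxelVolumeUm3(geometry(shbMask))
    shb <- maskArray(shbMask)
    both <- shb & maskArray(brpMask)
    rows <- lapply(names(regions), function(nm) {
        stopIfIncongruent(shbMask, regions[[nm]],
                          sprintf("ShB mask and region '%s'", nm))
        r <- maskArray(regions[[nm]])
        sv <- sum(shb & r) * vox
        ov <- sum(both & r) * vox
        pct <- if (sv > 0) 100 * ov / sv else {
            warning(sprintf("region '%s' holds no ShB signal; percent set to 0",
                            nm))
            0
        }
        data.frame(region = nm, shbVolume = sv, overlapVolume = ov,
                   percentColocalized = pct, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
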