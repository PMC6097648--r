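## Rank-filter morphology.  All filters act per-slice (2D) with a disc
## footprint: a pixel belongs to the disc iff its centre distance is
## <= radius; radius 1 is pinned to the full 3x3 square so that the
## 1-pixel outline is the 8-connected boundary shell.

#' Disc footprint offsets
#'
#' Row/column offsets of the 2D disc structuring element of a given
#' radius, as used by [rankFilter2D()].
#'
#' @param radius integer radius >= 1.
#' @return two-column integer matrix of (row, col) offsets.
#' @export
discOffsets <- function(radius) {
    radius <- as.integer(radius)
    if (radius < 1L) stop("radius must be >= 1")
    g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    if (radius > 1L) g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, ]
    as.matrix(g)
}

#' Per-slice disc minimum/maximum rank filter
#'
#' Filters every slice of a stack independently with a disc
#' neighbourhood; borders are handled by edge replication.  A minimum
#' filter is a grayscale erosion, a maximum filter a grayscale dilation;
#' the pair composes the opening used by [removeAgglomerations()].
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param radius disc radius in pixels (integer >= 1).
#' @param mode \code{"min"} or \code{"max"}.
#' @return filtered \linkS4class{VoxelStack}.
#' @examples
#' g <- voxelGeometry()
#' a <- array(0L, c(9, 9, 1)); a[5, 5, 1] <- 200L
#' vs <- voxelStack(a, g, "Brp")
#' max(intensities(rankFilter2D(vs, 3, "min")))  # 0: punctum erased
#' @export
rankFilter2D <- function(stack, radius, mode = c("min", "max")) {
    stopifnot(is(stack, "VoxelStack"))
    mode <- match.arg(mode)
    radius <- as.integer(radius)
    if (radius < 1L) stop("radius must be >= 1")
    a <- intensities(stack)
    out <- cpp_rank_disc2d(as.integer(a), dim(a), radius, mode == "max")
    voxelStack(array(out, dim(a)), geometry(stack), channelName(stack))
}

#' Remove bright labelling agglomerations by grayscale top-hat
#'
#' Large non-specific agglomerations of fluorescent fusion protein are
#' suppressed by a white top-hat: a minimum filter followed by a maximum
#' filter of the same disc radius (a grayscale opening) is subtracted
#' from the original with 8-bit saturating arithmetic.  Bright puncta
#' strictly smaller than the disc survive at full value; structures
#' wider than the disc are cancelled.  An optional linear contrast
#' rescale follows (on by default, flagged because histogram-shape
#' thresholds are not invariant to it).
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param radius disc radius in pixels; default 3.
#' @param rescale apply [rescaleContrast()] to the top-hat? default TRUE.
#' @return filtered \linkS4class{VoxelStack}.
#' @seealso [rankFilter2D()], [rescaleContrast()]
#' @export
removeAgglomerations <- function(stack, radius = 3L, rescale = TRUE) {
    opened <- rankFilter2D(rankFilter2D(stack, radius, "min"), radius, "max")
    a <- intensities(stack) - intensities(opened)
    a[a < 0L] <- 0L    # saturating subtraction; opening is anti-extensive
    out <- voxelStack(a, geometry(stack), channelName(stack))
    if (rescale) rescaleContrast(out) else out
}

#' One-pixel outline of a binary mask
#'
#' The per-slice boundary shell: mask AND NOT its radius-1 erosion
#' (3x3 footprint).  The outline's voxel volume divided by the pixel
#' size is the dendritic surface-area proxy (see [surfaceAreaProxy()]).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return a \linkS4class{BinaryMask} containing only boundary voxels.
#' @export
outline1px <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    a <- maskArray(mask)
    er <- cpp_rank_disc2d(as.integer(a), dim(a), 1L, FALSE)
    binaryMask(a & !array(as.logical(er), dim(a)), geometry(mask))
}

#' Linear min-max contrast stretch onto [0, 255]
#'
#' Whole-stack linear rescale; rounding is half-away-from-zero for
#' platform determinism.  Constant stacks are returned unchanged.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @return rescaled \linkS4class{VoxelStack}.
#' @export
rescaleContrast <- function(stack) {
    stopifnot(is(stack, "VoxelStack"))
    a <- intensities(stack)
    lo <- min(a); hi <- max(a)
    if (hi == lo) return(stack)
    ## integer numerator first: (50 * 255) / 100 is exactly 127.5,
    ## while 50 * (255 / 100) is not
    out <- array(as.integer(roundHalfUp(((a - lo) * 255) / (hi - lo))),
                 dim(a))
    voxelStack(out, geometry(stack), channelName(stack))
}
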