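#' Voxel geometry of a confocal stack
#'
#' Physical calibration and axis semantics of a 3D stack: in-plane pixel
#' pitch \code{dx}, \code{dy} and slice step \code{dz} (all micrometres),
#' which array axis runs anteroposteriorly (\code{apAxis}; slice index
#' increases anterior to posterior), and which sign along the mediolateral
#' axis points medially for this specimen's side (\code{medialDirection},
#' +1 or -1).  The default in-plane pitch is 0.22 um, the acquisition
#' pixel size the pipeline's boundary conversions assume.
#'
#' @slot dx,dy in-plane pixel size, um.
#' @slot dz slice step, um.
#' @slot apAxis integer in 1..3; array axis that is anteroposterior.
#' @slot medialDirection +1L or -1L; sign of increasing mediolateral index
#'   that points medially.
#'
#' @aliases geometry
#' @param dx,dy,dz voxel pitch in micrometres.
#' @param apAxis anteroposterior array axis (default 3, the slice axis).
#' @param medialDirection +1 or -1.
#' @param x a \code{VoxelStack}, \code{ChannelSet} or \code{BinaryMask}.
#' @return \code{voxelGeometry} returns a \code{VoxelGeometry} object.
#' @examples
#' voxelGeometry()                  # 0.22 x 0.22 x 1 um defaults
#' voxelGeometry(dz = 0.5, medialDirection = -1)
#' @export voxelGeometry
#' @exportClass VoxelGeometry
setClass("VoxelGeometry",
    representation(dx = "numeric", dy = "numeric", dz = "numeric",
                   apAxis = "integer", medialDirection = "integer"),
    validity = function(object) {
        p <- c(object@dx, object@dy, object@dz)
        if (length(p) != 3L || any(!is.finite(p)) || any(p <= 0))
            return("dx, dy, dz must be positive finite scalars")
        if (length(object@apAxis) != 1L || !object@apAxis %in% 1:3)
            return("apAxis must be 1, 2 or 3")
        if (length(object@medialDirection) != 1L ||
            !object@medialDirection %in% c(-1L, 1L))
            return("medialDirection must be +1 or -1")
        TRUE
    })

#' @rdname VoxelGeometry-class
voxelGeometry <- function(dx = 0.22, dy = dx, dz = 1, apAxis = 3L,
                          medialDirection = 1L) {
    new("VoxelGeometry", dx = dx, dy = dy, dz = dz,
        apAxis = as.integer(apAxis),
        medialDirection = as.integer(medialDirection))
}

voxelVolumeUm3 <- function(g) g@dx * g@dy * g@dz

geometryEqual <- function(a, b) {
    isTRUE(all.equal(c(a@dx, a@dy, a@dz), c(b@dx, b@dy, b@dz),
                     tolerance = 1e-6)) &&
        a@apAxis == b@apAxis && a@medialDirection == b@medialDirection
}

setMethod("show", "VoxelGeometry", function(object) {
    cat(sprintf("VoxelGeometry: %.4g x %.4g x %.4g um, AP axis %d, medial %+d\n",
                object@dx, object@dy, object@dz, object@apAxis,
                object@medialDirection))
})

#' Single-channel 3D 8-bit intensity stack
#'
#' One channel's voxel intensities (integers in 0..255) together with the
#' stack's \linkS4class{VoxelGeometry} and a channel label (for example
#' \code{"GF"}, \code{"NB"}, \code{"Brp"}, \code{"ShB"}).
#'
#' @slot intensities 3D integer array, values in 0..255.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot channelName single character label.
#'
#' @aliases intensities channelName
#' @param intensities 3D numeric/integer array with values in 0..255.
#' @param geometry a \code{VoxelGeometry}.
#' @param channelName label for the channel.
#' @param x a \code{VoxelStack}.
#' @return \code{voxelStack} returns a \code{VoxelStack}.
#' @examples
#' vs <- voxelStack(array(0L, c(4, 4, 2)), voxelGeometry(), "Brp")
#' dim(vs)
#' @export voxelStack
#' @exportClass VoxelStack
setClass("VoxelStack",
    representation(intensities = "array", geometry = "VoxelGeometry",
                   channelName = "character"),
    validity = function(object) {
        a <- object@intensities
        if (length(dim(a)) != 3L) return("intensities must be a 3D array")
        if (length(a) == 0L) return("stack must be nonempty")
        if (!is.integer(a)) return("intensities must have integer storage")
        r <- range(a)
        if (r[1] < 0L || r[2] > 255L)
            return("intensities must lie in [0, 255]")
        TRUE
    })

#' @rdname VoxelStack-class
voxelStack <- function(intensities, geometry = voxelGeometry(),
                       channelName = "") {
    a <- intensities
    if (!is.array(a) || length(dim(a)) != 3L)
        stop("intensities must be a 3D array")
    if (!is.integer(a)) {
        if (any(abs(a - round(a)) > 1e-8))
            stop("intensities must be whole numbers in [0, 255]")
        storage.mode(a) <- "integer"
    }
    new("VoxelStack", intensities = a, geometry = geometry,
        channelName = as.character(channelName))
}

setMethod("intensities", "VoxelStack", function(x) x@intensities)
setMethod("geometry", "VoxelStack", function(x) x@geometry)
setMethod("channelName", "VoxelStack", function(x) x@channelName)
#' @rdname VoxelStack-class
#' @export
setMethod("dim", "VoxelStack", function(x) dim(x@intensities))

setMethod("show", "VoxelStack", function(object) {
    d <- dim(object)
    cat(sprintf("VoxelStack '%s': %d x %d x %d voxels, range [%d, %d]\n",
                object@channelName, d[1], d[2], d[3],
                min(object@intensities), max(object@intensities)))
    show(object@geometry)
})

#' Named collection of congruent channels
#'
#' Channels of one specimen sharing a single shape and voxel geometry.
#' Subset with \code{[[} by channel name.
#'
#' @slot channels named list of \linkS4class{VoxelStack}.
#'
#' @aliases channelNames
#' @param channels named list of \code{VoxelStack} objects.
#' @param x a \code{ChannelSet}.
#' @param i channel name or index.
#' @return \code{channelSet} returns a \code{ChannelSet}.
#' @examples
#' g <- voxelGeometry()
#' cs <- channelSet(list(
#'     Brp = voxelStack(array(0L, c(4, 4, 2)), g, "Brp"),
#'     GF  = voxelStack(array(0L, c(4, 4, 2)), g, "GF")))
#' channelNames(cs)
#' @export channelSet
#' @exportClass ChannelSet
setClass("ChannelSet",
    representation(channels = "list"),
    validity = function(object) {
        ch <- object@channels
        if (length(ch) == 0L) return("at least one channel required")
        if (is.null(names(ch)) || any(!nzchar(names(ch))) ||
            anyDuplicated(names(ch)))
            return("channels must have unique nonempty names")
        if (!all(vapply(ch, is, logical(1), "VoxelStack")))
            return("all channels must be VoxelStack objects")
        d0 <- dim(ch[[1]])
        g0 <- geometry(ch[[1]])
        for (k in seq_along(ch)) {
            if (!identical(dim(ch[[k]]), d0))
                return(sprintf("channel '%s' shape %s differs from '%s' shape %s",
                               names(ch)[k], paste(dim(ch[[k]]), collapse = "x"),
                               names(ch)[1], paste(d0, collapse = "x")))
            if (!geometryEqual(geometry(ch[[k]]), g0))
                return(sprintf("channel '%s' geometry differs", names(ch)[k]))
        }
        TRUE
    })

#' @rdname ChannelSet-class
channelSet <- function(channels) new("ChannelSet", channels = channels)

setMethod("channelNames", "ChannelSet", function(x) names(x@channels))
setMethod("geometry", "ChannelSet", function(x) geometry(x@channels[[1]]))
#' @rdname ChannelSet-class
#' @export
setMethod("dim", "ChannelSet", function(x) dim(x@channels[[1]]))

#' @rdname ChannelSet-class
#' @export
setMethod("[[", "ChannelSet", function(x, i) {
    if (is.character(i) && !i %in% names(x@channels))
        stop(sprintf("unknown channel '%s'; available: %s", i,
                     paste(names(x@channels), collapse = ", ")),
             call. = FALSE)
    x@channels[[i]]
})

setMethod("show", "ChannelSet", function(object) {
    d <- dim(object)
    cat(sprintf("ChannelSet: %d channel(s) [%s], %d x %d x %d voxels\n",
                length(object@channels),
                paste(names(object@channels), collapse = ", "),
                d[1], d[2], d[3]))
    show(geometry(object))
})

#' Binary voxel mask
#'
#' A 3D logical grid congruent with the stack it was derived from, the
#' product of thresholding or of manual annotation.
#'
#' @slot voxels 3D logical array.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#'
#' @aliases maskArray maskVolume
#' @param voxels 3D logical array.
#' @param geometry a \code{VoxelGeometry}.
#' @param x a \code{BinaryMask}.
#' @return \code{binaryMask} returns a \code{BinaryMask};
#'   \code{maskVolume} its foreground volume in um^3.
#' @examples
#' m <- binaryMask(array(TRUE, c(3, 3, 2)), voxelGeometry())
#' maskVolume(m)   # 18 voxels x 0.22 x 0.22 x 1 um
#' @export binaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
    representation(voxels = "array", geometry = "VoxelGeometry"),
    validity = function(object) {
        if (length(dim(object@voxels)) != 3L)
            return("voxels must be a 3D array")
        if (!is.logical(object@voxels)) return("voxels must be logical")
        TRUE
    })

#' @rdname BinaryMask-class
binaryMask <- function(voxels, geometry = voxelGeometry()) {
    new("BinaryMask", voxels = voxels, geometry = geometry)
}

setMethod("maskArray", "BinaryMask", function(x) x@voxels)
setMethod("geometry", "BinaryMask", function(x) x@geometry)
#' @rdname BinaryMask-class
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@voxels))
setMethod("maskVolume", "BinaryMask",
          function(x) sum(x@voxels) * voxelVolumeUm3(x@geometry))

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object)
    cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.4g um^3)\n",
                d[1], d[2], d[3], sum(object@voxels), maskVolume(object)))
})

#' Pooled 256-bin stack histogram
#'
#' Intensity histogram pooled over all slices of an 8-bit stack, the
#' substrate of the auto-threshold algorithms.  With \code{ignoreWhite}
#' bin 255 is zeroed and its count recorded separately, mirroring the
#' "Ignore white" option of common thresholding tools.
#'
#' @slot counts integer vector of length 256 (bins 0..255).
#' @slot ignoreWhite logical flag.
#' @slot sourceVoxels number of voxels pooled.
#' @slot excludedWhite number of value-255 voxels excluded.
#'
#' @export intensityHistogram
#' @exportClass IntensityHistogram
#' @param counts integer vector of length 256.
#' @param ignoreWhite was bin 255 excluded?
#' @param sourceVoxels,excludedWhite bookkeeping counts.
setClass("IntensityHistogram",
    representation(counts = "integer", ignoreWhite = "logical",
                   sourceVoxels = "numeric", excludedWhite = "numeric"),
    validity = function(object) {
        if (length(object@counts) != 256L)
            return("counts must have length 256")
        if (any(object@counts < 0L)) return("counts must be nonnegative")
        if (sum(object@counts) + object@excludedWhite != object@sourceVoxels)
            return("counts + excluded white must equal source voxels")
        TRUE
    })

#' @rdname IntensityHistogram-class
intensityHistogram <- function(counts, ignoreWhite = TRUE,
                               sourceVoxels = sum(counts), excludedWhite = 0) {
    new("IntensityHistogram", counts = as.integer(counts),
        ignoreWhite = ignoreWhite, sourceVoxels = as.numeric(sourceVoxels),
        excludedWhite = as.numeric(excludedWhite))
}

setMethod("show", "IntensityHistogram", function(object) {
    cat(sprintf("IntensityHistogram: %g voxels, %d nonzero bins%s\n",
                object@sourceVoxels, sum(object@counts > 0L),
                if (object@ignoreWhite)
                    sprintf(", %g white excluded", object@excludedWhite)
                else ""))
})

#' Auto-threshold result
#'
#' The level chosen by one of the histogram auto-threshold methods,
#' with the method name and iteration/diagnostic details.  Foreground is
#' defined as intensity strictly greater than \code{level}.
#'
#' @slot level integer threshold in 0..255.
#' @slot method one of \code{"intermodes"}, \code{"default_isodata"},
#'   \code{"renyi_entropy"}.
#' @slot iterations iterations used (smoothing passes or fixed-point steps).
#' @slot diagnostics method-specific list (for example the three Renyi
#'   candidate levels).
#'
#' @aliases level
#' @param x a \code{ThresholdResult}.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
    representation(level = "integer", method = "character",
                   iterations = "integer", diagnostics = "list"),
    validity = function(object) {
        if (object@level < 0L || object@level > 255L)
            return("level must lie in [0, 255]")
        TRUE
    })

thresholdResult <- function(level, method, iterations = 0L,
                            diagnostics = list()) {
    new("ThresholdResult", level = as.integer(level), method = method,
        iterations = as.integer(iterations), diagnostics = diagnostics)
}

setMethod("level", "ThresholdResult", function(x) x@level)

setMethod("show", "ThresholdResult", function(object) {
    cat(sprintf("ThresholdResult: level %d (%s, %d iterations)\n",
                object@level, object@method, object@iterations))
})

#' Per-slice foreground area profile
#'
#' Foreground area of a binary mask per slice (um^2) and the total
#' foreground volume (um^3 = sum of areas times the slice step).
#'
#' @slot areas numeric vector, one area per slice (um^2).
#' @slot dz slice step, um.
#' @slot totalVolume foreground volume, um^3.
#'
#' @aliases sliceAreas totalVolume
#' @param x a \code{SliceProfile}.
#' @exportClass SliceProfile
setClass("SliceProfile",
    representation(areas = "numeric", dz = "numeric",
                   totalVolume = "numeric"),
    validity = function(object) {
        if (!isTRUE(all.equal(sum(object@areas) * object@dz,
                              object@totalVolume, tolerance = 1e-8)))
            return("totalVolume must equal sum(areas) * dz")
        TRUE
    })

setMethod("sliceAreas", "SliceProfile", function(x) x@areas)
setMethod("totalVolume", "SliceProfile", function(x) x@totalVolume)

setMethod("show", "SliceProfile", function(object) {
    cat(sprintf("SliceProfile: %d slices, total %.4g um^3\n",
                length(object@areas), object@totalVolume))
})

#' Per-specimen quantification summary
#'
#' All derived measures for one specimen: active-zone-on-GF volume,
#' GF surface-area proxy, medial branch measures, Neurobiotin coupling
#' area, and per-region ShakB volumes/colocalization.
#'
#' @slot specimenId specimen identifier.
#' @slot measures named numeric vector of scalar measures.
#' @slot regions data.frame of per-region ShakB/Brp colocalization
#'   (columns region, shbVolume, overlapVolume, percentColocalized).
#'
#' @aliases measures
#' @param x a \code{QuantSummary}.
#' @param row.names,optional,... passed on for the data.frame method.
#' @exportClass QuantSummary
setClass("QuantSummary",
    representation(specimenId = "character", measures = "numeric",
                   regions = "data.frame"))

quantSummary <- function(specimenId, measures, regions = emptyRegionTable()) {
    new("QuantSummary", specimenId = specimenId, measures = measures,
        regions = regions)
}

emptyRegionTable <- function() {
    data.frame(region = character(), shbVolume = numeric(),
               overlapVolume = numeric(), percentColocalized = numeric(),
               stringsAsFactors = FALSE)
}

setMethod("measures", "QuantSummary", function(x) x@measures)

setMethod("show", "QuantSummary", function(object) {
    cat(sprintf("QuantSummary '%s':\n", object@specimenId))
    m <- object@measures
    for (k in seq_along(m))
        cat(sprintf("  %-24s %.5g\n", names(m)[k], m[k]))
    if (nrow(object@regions)) {
        cat("  per-region colocalization:\n")
        print(object@regions, row.names = FALSE)
    }
})

#' @describeIn QuantSummary-class flatten to a one-row data.frame
#'   (region columns suffixed by region name).
#' @export
as.data.frame.QuantSummary <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    out <- data.frame(specimenId = x@specimenId, t(x@measures),
                      stringsAsFactors = FALSE)
    if (nrow(x@regions)) {
        for (i in seq_len(nrow(x@regions))) {
            r <- x@regions$region[i]
            out[[paste0("shbVolume_", r)]] <- x@regions$shbVolume[i]
            out[[paste0("shbBrpOverlap_", r)]] <- x@regions$overlapVolume[i]
            out[[paste0("percentColoc_", r)]] <- x@regions$percentColocalized[i]
        }
    }
    out
}

#' Group-comparison statistics for one measure
#'
#' Shapiro-Wilk normality per group, one-way ANOVA, Tukey(-Kramer) HSD
#' pairwise comparisons with significance stars, and group means with
#' SEM (sd/sqrt(N), N = animals).
#'
#' @slot measure measure name.
#' @slot normality data.frame: group, n, W, p.
#' @slot anova data.frame: dfBetween, dfWithin, F, p.
#' @slot tukey data.frame: comparison, diff, lwr, upr, p, stars.
#' @slot groupMeans data.frame: group, n, mean, sem.
#'
#' @exportClass StatsReport
setClass("StatsReport",
    representation(measure = "character", normality = "data.frame",
                   anova = "data.frame", tukey = "data.frame",
                   groupMeans = "data.frame"))

setMethod("show", "StatsReport", function(object) {
    cat(sprintf("StatsReport for '%s'\n", object@measure))
    cat(sprintf("  ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
                object@anova$dfBetween, object@anova$dfWithin,
                object@anova$F, object@anova$p))
    cat("  Tukey HSD:\n")
    print(object@tukey, row.names = FALSE)
    cat("  Group means +/- SEM:\n")
    print(object@groupMeans, row.names = FALSE)
})
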