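## Synthetic confocal phantoms of the JON -> GF circuit.  The scene is a
## tubular GF dendrite with medial branches, ~1 um ShakB plaques split
## between JO-A and JO-B territories (a fraction colocalized with Brp),
## sub-micron Brp puncta (a subset apposed to the dendrite as putative
## active zones), large non-specific agglomerations present only in the
## Brp-short channel, and Neurobiotin label filling the dendrite plus a
## subset of coupled axons.  Rendering is followed by separable Gaussian
## PSF blur, Poisson shot noise plus Gaussian read noise, and 8-bit
## quantization at 0.22 um pixels.

#' Phantom specification
#'
#' All geometric and photometric parameters of one synthetic specimen.
#' Lengths and diameters are micrometres, intensities 8-bit units.
#' The defaults emulate the acquisition regime the pipeline targets:
#' 0.22 x 0.22 x 1 um voxels, 1-um gap-junction plaques with a
#' four-to-one JO-A/JO-B split and roughly one-fifth of plaque volume
#' colocalized with Brp, sub-micron Brp puncta, agglomeration blobs of
#' >= 3 um, and shot plus read noise giving punctate-structure SNR
#' near 20 (high enough that the Brp top-hat histogram stays reliably
#' bimodal for Intermodes thresholding).
#'
#' @slot dims stack shape (rows = dorsoventral, cols = mediolateral,
#'   slices = anteroposterior).
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot dendriteRadius,dendriteIntensity GF dendrite tube.
#' @slot branchLengthsUm,branchRadius medial branch lengths (from the
#'   dendrite centreline) and radius.
#' @slot plaqueCountA,plaqueCountB,plaqueDiameter,plaqueIntensity ShakB
#'   plaques per territory.
#' @slot shbColocFractionA,shbColocFractionB fraction of plaques per
#'   territory carrying a colocalized Brp punctum.
#' @slot punctumCount,punctumDiameter,punctumIntensity scattered Brp
#'   puncta.
#' @slot azCount,azDiameter Brp puncta apposed to the dendrite surface
#'   (putative active zones on the GF).
#' @slot agglomCount,agglomDiameter,agglomIntensity artifact blobs
#'   (Brp-short channel only).
#' @slot nbAxonCount,axonRadius,nbIntensity Neurobiotin-coupled axons.
#' @slot psfSigmaXY,psfSigmaZ Gaussian PSF sigmas, um (0 = no blur).
#' @slot poissonScale photons per intensity unit (0 = no shot noise).
#' @slot readNoiseSd Gaussian read noise sd, 8-bit units (0 = none).
#' @slot seed integer seed fixing the full realization.
#'
#' @param ... slot values overriding the defaults (see slots above).
#' @return \code{phantomSpec} returns a \code{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(dims = c(64L, 64L, 24L), seed = 7L)
#' @export phantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(dims = "integer", geometry = "VoxelGeometry",
                   dendriteRadius = "numeric", dendriteIntensity = "numeric",
                   branchLengthsUm = "numeric", branchRadius = "numeric",
                   plaqueCountA = "integer", plaqueCountB = "integer",
                   plaqueDiameter = "numeric", plaqueIntensity = "numeric",
                   shbColocFractionA = "numeric",
                   shbColocFractionB = "numeric",
                   punctumCount = "integer", punctumDiameter = "numeric",
                   punctumIntensity = "numeric", azCount = "integer",
                   azDiameter = "numeric",
                   agglomCount = "integer", agglomDiameter = "numeric",
                   agglomIntensity = "numeric", nbAxonCount = "integer",
                   axonRadius = "numeric", nbIntensity = "numeric",
                   psfSigmaXY = "numeric", psfSigmaZ = "numeric",
                   poissonScale = "numeric", readNoiseSd = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@dims) != 3L || any(object@dims < 8L))
            return("dims must be three integers >= 8")
        pos <- c(object@dendriteRadius, object@branchRadius,
                 object@plaqueDiameter, object@punctumDiameter,
                 object@azDiameter, object@agglomDiameter,
                 object@axonRadius)
        if (any(pos <= 0)) return("all sizes must be positive")
        fr <- c(object@shbColocFractionA, object@shbColocFractionB)
        if (any(fr < 0 | fr > 1))
            return("colocalization fractions must lie in [0, 1]")
        if (any(c(object@psfSigmaXY, object@psfSigmaZ,
                  object@poissonScale, object@readNoiseSd) < 0))
            return("PSF sigmas and noise parameters must be >= 0")
        TRUE
    })

#' @rdname PhantomSpec-class
phantomSpec <- function(...) {
    defaults <- list(
        dims = c(128L, 128L, 60L), geometry = voxelGeometry(),
        dendriteRadius = 1.4, dendriteIntensity = 200,
        branchLengthsUm = c(3, 4.5, 5.5, 6.5), branchRadius = 0.5,
        plaqueCountA = 24L, plaqueCountB = 6L,
        plaqueDiameter = 1, plaqueIntensity = 180,
        shbColocFractionA = 0.22, shbColocFractionB = 0.17,
        punctumCount = 150L, punctumDiameter = 0.9, punctumIntensity = 200,
        azCount = 25L, azDiameter = 0.8,
        agglomCount = 3L, agglomDiameter = 4, agglomIntensity = 220,
        nbAxonCount = 5L, axonRadius = 0.8, nbIntensity = 190,
        psfSigmaXY = 0.08, psfSigmaZ = 0.35,
        poissonScale = 2, readNoiseSd = 4, seed = 1L)
    args <- list(...)
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stop(sprintf("unknown PhantomSpec field(s): %s",
                     paste(unknown, collapse = ", ")))
    vals <- modifyList(defaults, args)
    for (f in c("dims", "plaqueCountA", "plaqueCountB", "punctumCount",
                "azCount", "agglomCount", "nbAxonCount", "seed"))
        vals[[f]] <- as.integer(vals[[f]])
    do.call(new, c(list("PhantomSpec"), vals))
}

#' Ground truth of a phantom
#'
#' Structure-class masks, true volumes and object counts emitted by
#' [generatePhantom()], used for recovery tests of the pipeline.
#'
#' @slot masks named list of \linkS4class{BinaryMask} (gf, branches,
#'   plaquesA, plaquesB, puncta, az, agglomerations, nbAxons, nb, joA,
#'   joB).
#' @slot volumes named numeric, um^3 (pre-noise foreground volumes).
#' @slot counts named numeric object counts.
#'
#' @exportClass PhantomTruth
setClass("PhantomTruth",
    representation(masks = "list", volumes = "numeric", counts = "numeric"))

setMethod("show", "PhantomTruth", function(object) {
    cat("PhantomTruth:\n  volumes (um^3):\n")
    v <- object@volumes
    for (k in seq_along(v))
        cat(sprintf("    %-16s %.4g\n", names(v)[k], v[k]))
})

## --- rendering primitives (voxel-centre physical coordinates) --------

## Max-composite spheres of common radius into a canvas; centers is an
## n x 3 matrix of physical (y, x, z) um.  Errors if any sphere leaves
## the stack, naming the object.
renderSpheres <- function(canvas, g, centers, R, intensity, what) {
    if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
    if (nrow(centers) == 0L) return(canvas)
    d <- dim(canvas)
    ext <- (d - 1L) * c(g@dy, g@dx, g@dz)
    lo <- sweep(centers, 2, rep(R, 3))
    hi <- sweep(centers, 2, rep(R, 3), "+")
    if (any(lo < -1e-9) || any(t(t(hi) - ext) > 1e-9))
        stop(sprintf("object out of bounds: %s", what), call. = FALSE)
    array(cpp_render_spheres(canvas, d, c(g@dy, g@dx, g@dz), centers, R,
                             intensity), d)
}

## Centre samples of a capsule (swept sphere) along a segment, spaced
## at half the finest pitch.
capsuleCenters <- function(g, from, to) {
    len <- sqrt(sum((to - from)^2))
    step <- min(g@dx, g@dy, g@dz) / 2
    n <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = n)
    cbind(from[1] + t * (to[1] - from[1]),
          from[2] + t * (to[2] - from[2]),
          from[3] + t * (to[3] - from[3]))
}

## Minimum euclidean distance from a point to a set of segments
## (rows of segs are c(from, to) in physical um).
minSegmentDistance <- function(p, segs) {
    dmin <- Inf
    for (i in seq_len(nrow(segs))) {
        a <- segs[i, 1:3]
        b <- segs[i, 4:6]
        ab <- b - a
        t <- sum((p - a) * ab) / sum(ab * ab)
        t <- min(max(t, 0), 1)
        dmin <- min(dmin, sqrt(sum((p - (a + t * ab))^2)))
    }
    dmin
}

blurPSF <- function(canvas, g, sigmaXY, sigmaZ) {
    d <- dim(canvas)
    gauss <- function(sigmaPx) {
        if (sigmaPx < 1e-9) return(NULL)
        half <- max(1L, ceiling(3 * sigmaPx))
        k <- exp(-((-half:half)^2) / (2 * sigmaPx^2))
        k / sum(k)
    }
    ks <- list(gauss(sigmaXY / g@dy), gauss(sigmaXY / g@dx),
               gauss(sigmaZ / g@dz))
    for (ax in 1:3) {
        if (!is.null(ks[[ax]]))
            canvas <- array(cpp_conv1d_axis(canvas, d, ks[[ax]], ax - 1L), d)
    }
    canvas
}

applyNoise <- function(canvas, poissonScale, readNoiseSd) {
    if (poissonScale > 0) {
        idx <- which(canvas > 0)
        if (length(idx))
            canvas[idx] <- rpois(length(idx), canvas[idx] * poissonScale) /
                poissonScale
    }
    if (readNoiseSd > 0)
        canvas <- canvas + rnorm(length(canvas), 0, readNoiseSd)
    canvas
}

quantize8bit <- function(canvas, d) {
    q <- roundHalfUp(canvas)
    q[q < 0] <- 0
    q[q > 255] <- 255
    array(as.integer(q), d)
}

## n uniform random physical positions inside the stack with a margin
## (um); optionally restricted to one side of the dividing plane at
## mediolateral coordinate centerX.
randomCenters <- function(n, d, g, margin, side = NULL, centerX = NULL,
                          medialDir = 1L) {
    ext <- (d - 1L) * c(g@dy, g@dx, g@dz)
    if (any(ext <= 2 * margin))
        stop("stack too small for requested object size", call. = FALSE)
    y <- runif(n, margin, ext[1] - margin)
    z <- runif(n, margin, ext[3] - margin)
    if (is.null(side)) {
        x <- runif(n, margin, ext[2] - margin)
    } else if ((side == "medial") == (medialDir > 0)) {
        x <- runif(n, min(centerX + 0.5, ext[2] - margin), ext[2] - margin)
    } else {
        x <- runif(n, margin, max(centerX - 0.5, margin))
    }
    cbind(y, x, z)
}

#' Generate one synthetic specimen with ground truth
#'
#' Renders the phantom scene defined by a \linkS4class{PhantomSpec},
#' applies Gaussian PSF blur, Poisson + Gaussian noise and 8-bit
#' quantization, and returns the channels (\code{GF}, \code{NB},
#' \code{Brp}, \code{nc82}, \code{ShB}) together with a
#' \linkS4class{PhantomTruth}.  Agglomeration blobs appear in the
#' Brp-short channel but never in the nc82-like channel.  The seed in
#' the spec fixes the full realization.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{channels} (a
#'   \linkS4class{ChannelSet}) and \code{truth} (a
#'   \linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    set.seed(spec@seed)
    d <- spec@dims
    g <- spec@geometry
    ext <- (d - 1L) * c(g@dy, g@dx, g@dz)
    mdir <- g@medialDirection

    zero <- array(0, d)

    ## -- GF dendrite: gentle mediolateral sweep along the AP axis ----
    zTipFrac <- 0.2
    zEndFrac <- 0.85
    yMid <- ext[1] / 2
    xMid <- if (mdir > 0) 0.32 * ext[2] else 0.68 * ext[2]
    ctrl <- rbind(
        c(yMid, xMid - mdir * 0.03 * ext[2], zTipFrac * ext[3]),
        c(yMid, xMid, 0.5 * ext[3]),
        c(yMid, xMid + mdir * 0.03 * ext[2], zEndFrac * ext[3]))
    dendCenters <- rbind(capsuleCenters(g, ctrl[1, ], ctrl[2, ]),
                         capsuleCenters(g, ctrl[2, ], ctrl[3, ]))
    dendrite <- renderSpheres(zero, g, dendCenters, spec@dendriteRadius,
                              spec@dendriteIntensity, "GF dendrite")

    ## -- medial branches from the mid region of the dendrite ---------
    branches <- zero
    nBr <- length(spec@branchLengthsUm)
    if (nBr > 0L) {
        zs <- seq(0.4, 0.7, length.out = nBr) * ext[3]
        for (i in seq_len(nBr)) {
            from <- c(yMid, xMid, zs[i])
            to <- from + c(0, mdir * spec@branchLengthsUm[i], 0)
            branches <- renderSpheres(branches, g, capsuleCenters(g, from, to),
                                      spec@branchRadius,
                                      spec@dendriteIntensity,
                                      sprintf("medial branch %d", i))
        }
    }
    gfCanvas <- pmax(dendrite, branches)
    gfTruth <- gfCanvas > 0

    ## -- ShakB plaques split between the territories -----------------
    ## Plaques (and the Brp puncta colocalized with them) are kept off
    ## the GF dendrite and its branches: the pipeline's dissociation
    ## property — a ShakB-only group effect must not move AZ-on-GF —
    ## holds only if plaque-linked Brp never touches the GF.
    segs <- rbind(cbind(ctrl[-nrow(ctrl), , drop = FALSE],
                        ctrl[-1, , drop = FALSE]))
    if (nBr > 0L) {
        for (i in seq_len(nBr)) {
            from <- c(yMid, xMid, zs[i])
            to <- from + c(0, mdir * spec@branchLengthsUm[i], 0)
            segs <- rbind(segs, c(from, to))
        }
    }
    plaqueR <- spec@plaqueDiameter / 2
    keepOff <- spec@dendriteRadius + 1.2 * plaqueR + 0.4
    drawPlaques <- function(n, side) {
        out <- matrix(0, 0, 3)
        tries <- 0L
        while (nrow(out) < n) {
            tries <- tries + 1L
            if (tries > 200L * n)
                stop("cannot place plaques off the dendrite", call. = FALSE)
            ctr <- randomCenters(1L, d, g, plaqueR + 0.3, side, xMid, mdir)
            if (minSegmentDistance(ctr, segs) > keepOff)
                out <- rbind(out, ctr)
        }
        out
    }
    ctrA <- drawPlaques(spec@plaqueCountA, "lateral")
    ctrB <- drawPlaques(spec@plaqueCountB, "medial")
    plaquesA <- renderSpheres(zero, g, ctrA, plaqueR,
                              spec@plaqueIntensity, "ShB plaque (JO-A)")
    plaquesB <- renderSpheres(zero, g, ctrB, plaqueR,
                              spec@plaqueIntensity, "ShB plaque (JO-B)")
    shbCanvas <- pmax(plaquesA, plaquesB)

    ## -- Brp puncta: scattered, colocalized-with-plaque, and active
    ##    zones on the GF surface --------------------------------------
    punctumR <- spec@punctumDiameter / 2
    scatter <- randomCenters(spec@punctumCount, d, g, punctumR + 0.3)
    puncta <- renderSpheres(zero, g, scatter, punctumR,
                            spec@punctumIntensity, "Brp punctum")
    colocA <- ctrA[runif(nrow(ctrA)) < spec@shbColocFractionA, , drop = FALSE]
    colocB <- ctrB[runif(nrow(ctrB)) < spec@shbColocFractionB, , drop = FALSE]
    ## a Brp punctum slightly larger than the plaque, centred on it,
    ## makes that plaque ~fully colocalized even after blur and
    ## thresholding, so the expected percent-colocalized per territory
    ## tracks the coloc fraction
    puncta <- renderSpheres(puncta, g, rbind(colocA, colocB), 1.2 * plaqueR,
                            spec@plaqueIntensity, "colocalized Brp punctum")
    az <- zero
    if (spec@azCount > 0L) {
        azR <- spec@azDiameter / 2
        zAz <- runif(spec@azCount, zTipFrac * ext[3] + 1,
                     zEndFrac * ext[3] - 1)
        phi <- runif(spec@azCount, 0, 2 * pi)
        ## follow the swept centreline so every AZ sits on the surface
        xLocal <- stats::approx(ctrl[, 3], ctrl[, 2], xout = zAz,
                                rule = 2)$y
        azCtr <- cbind(yMid + spec@dendriteRadius * cos(phi),
                       xLocal + spec@dendriteRadius * sin(phi),
                       zAz)
        az <- renderSpheres(zero, g, azCtr, azR, spec@punctumIntensity,
                            "active zone")
    }

    ## -- agglomerations: Brp-short channel only ----------------------
    agglomR <- spec@agglomDiameter / 2
    agglomCtr <- randomCenters(spec@agglomCount, d, g, agglomR + 0.3)
    agglom <- renderSpheres(zero, g, agglomCtr, agglomR,
                            spec@agglomIntensity, "agglomeration")
    nc82Canvas <- pmax(puncta, az)
    brpCanvas <- pmax(nc82Canvas, agglom)

    ## -- Neurobiotin: fills the dendrite plus coupled axons ----------
    axons <- zero
    if (spec@nbAxonCount > 0L) {
        for (i in seq_len(spec@nbAxonCount)) {
            yA <- runif(1, 0.2 * ext[1], 0.8 * ext[1])
            latRoom <- if (mdir > 0) xMid else ext[2] - xMid
            xOff <- runif(1, 1.2, latRoom - spec@axonRadius - 0.5)
            xA <- xMid - mdir * xOff          # lateral (JO-A) side
            from <- c(yA, xA, spec@axonRadius + 0.2)
            to <- c(yA, xA, min(0.75 * ext[3], ext[3] - spec@axonRadius - 0.2))
            axons <- renderSpheres(axons, g, capsuleCenters(g, from, to),
                                   spec@axonRadius, spec@nbIntensity,
                                   sprintf("NB axon %d", i))
        }
    }
    nbCanvas <- pmax((gfCanvas > 0) * spec@nbIntensity, axons)

    ## -- territories: dividing plane at the dendrite centre ----------
    xIndex <- (slice.index(zero, 2L) - 1L) * g@dx
    joA <- (xIndex - xMid) * mdir < 0
    joB <- !joA

    ## -- optics, noise, quantization ---------------------------------
    mk <- function(canvas, name) {
        canvas <- blurPSF(canvas, g, spec@psfSigmaXY, spec@psfSigmaZ)
        canvas <- applyNoise(canvas, spec@poissonScale, spec@readNoiseSd)
        voxelStack(quantize8bit(canvas, d), g, name)
    }
    channels <- channelSet(list(
        GF = mk(gfCanvas, "GF"), NB = mk(nbCanvas, "NB"),
        Brp = mk(brpCanvas, "Brp"), nc82 = mk(nc82Canvas, "nc82"),
        ShB = mk(shbCanvas, "ShB")))

    vox <- voxelVolumeUm3(g)
    masks <- list(
        gf = binaryMask(gfTruth, g),
        branches = binaryMask(branches > 0, g),
        plaquesA = binaryMask(plaquesA > 0, g),
        plaquesB = binaryMask(plaquesB > 0, g),
        puncta = binaryMask(puncta > 0, g),
        az = binaryMask(az > 0, g),
        agglomerations = binaryMask(agglom > 0, g),
        nbAxons = binaryMask(axons > 0, g),
        nb = binaryMask(nbCanvas > 0, g),
        joA = binaryMask(joA, g),
        joB = binaryMask(joB, g))
    volumes <- vapply(masks, function(m) sum(maskArray(m)) * vox, numeric(1))
    counts <- c(plaquesA = spec@plaqueCountA, plaquesB = spec@plaqueCountB,
                puncta = spec@punctumCount, az = spec@azCount,
                agglomerations = spec@agglomCount,
                nbAxons = spec@nbAxonCount,
                colocalizedPlaquesA = nrow(colocA),
                colocalizedPlaquesB = nrow(colocB))
    storage.mode(counts) <- "double"
    truth <- new("PhantomTruth", masks = masks, volumes = volumes,
                 counts = counts)
    list(channels = channels, truth = truth)
}
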