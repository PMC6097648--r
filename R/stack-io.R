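## Stack and mask I/O.  All files are plain multi-page grayscale TIFF:
## one file per channel, pages are slices ordered anterior -> posterior.

readPages <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                                 call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) p[, , 1L] else p   # collapse RGB greys
    })
    arr <- array(0L, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (s in seq_along(pages)) arr[, , s] <- pages[[s]]
    storage.mode(arr) <- "integer"
    arr
}

#' Read a multi-channel stack from per-channel TIFF files
#'
#' Reads one multi-page grayscale TIFF per channel into a congruent
#' \linkS4class{ChannelSet}.  8-bit files are read as stored; 16-bit
#' files are linearly rescaled onto 0..255 with a warning.  Channels of
#' differing shape are a hard error naming both shapes; requesting a
#' channel that is not on offer is a hard error listing what is.
#'
#' @param paths named character vector mapping channel labels to TIFF
#'   file paths (the channels available).
#' @param channelMap character vector of channel labels to load
#'   (default: all available).
#' @param geometry a \linkS4class{VoxelGeometry} shared by all channels.
#' @return a \linkS4class{ChannelSet}.
#' @seealso [writeChannelSet()], [readMask()]
#' @export
readChannelSet <- function(paths, channelMap = names(paths),
                           geometry = voxelGeometry()) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
        stop("paths must be a named character vector of channel files")
    missing <- setdiff(channelMap, names(paths))
    if (length(missing))
        stop(sprintf("channel(s) %s not present; available channels: %s",
                     paste(sQuote(missing), collapse = ", "),
                     paste(sQuote(names(paths)), collapse = ", ")),
             call. = FALSE)
    chans <- list()
    for (nm in channelMap) {
        arr <- readPages(paths[[nm]])
        if (max(arr) > 255L) {
            warning(sprintf("channel '%s' is 16-bit; linearly rescaled to 8-bit",
                            nm))
            arr <- array(as.integer(roundHalfUp(arr * (255 / 65535))),
                         dim(arr))
        }
        chans[[nm]] <- voxelStack(arr, geometry, nm)
        if (length(chans) > 1L && !identical(dim(chans[[nm]]), dim(chans[[1]])))
            stop(sprintf("channel '%s' shape %s does not match channel '%s' shape %s",
                         nm, paste(dim(chans[[nm]]), collapse = "x"),
                         channelMap[1], paste(dim(chans[[1]]), collapse = "x")),
                 call. = FALSE)
    }
    channelSet(chans)
}

#' Write a ChannelSet to per-channel 8-bit multi-page TIFF files
#'
#' @param set a \linkS4class{ChannelSet}.
#' @param paths named character vector (one path per channel to write;
#'   default channels of \code{set}, which must then all be named in
#'   \code{paths}).
#' @return invisibly, the paths written.
#' @export
writeChannelSet <- function(set, paths) {
    stopifnot(is(set, "ChannelSet"))
    missing <- setdiff(names(paths), channelNames(set))
    if (length(missing))
        stop(sprintf("set has no channel(s) %s",
                     paste(sQuote(missing), collapse = ", ")))
    for (nm in names(paths)) {
        a <- intensities(set[[nm]])
        pages <- lapply(seq_len(dim(a)[3]), function(s) a[, , s] / 255)
        tiff::writeTIFF(pages, paths[[nm]], bits.per.sample = 8L)
    }
    invisible(paths)
}

#' Read or write a binary mask TIFF
#'
#' Masks are single-channel 8-bit TIFFs with 0 = background and 255 =
#' foreground; any other nonzero value reads as foreground with a
#' warning (tolerant of annotation tools that write 1 or 128).
#'
#' @param path TIFF file path.
#' @param geometry a \linkS4class{VoxelGeometry} for the mask.
#' @return \code{readMask} returns a \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, geometry = voxelGeometry()) {
    arr <- readPages(path)
    odd <- arr != 0L & arr != 255L
    if (any(odd))
        warning(sprintf("%d mask voxels are neither 0 nor 255; read as foreground",
                        sum(odd)))
    binaryMask(arr != 0L, geometry)
}

#' @rdname readMask
#' @param mask a \linkS4class{BinaryMask} to write.
#' @export
writeMask <- function(mask, path) {
    a <- maskArray(mask)
    pages <- lapply(seq_len(dim(a)[3]), function(s) a[, , s] * 1)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    invisible(path)
}

#' Restrict a ChannelSet to a region of interest
#'
#' Zeroes every voxel outside the ROI mask in every channel, the digital
#' analogue of trimming the stack to the afferent axons and the primary
#' GF dendrite before quantification.  Geometry is unchanged.
#'
#' @param set a \linkS4class{ChannelSet}.
#' @param roiMask a congruent \linkS4class{BinaryMask}.
#' @return a \linkS4class{ChannelSet} with out-of-ROI voxels set to 0.
#' @seealso [subtractMaskRegion()] for the complementary operation.
#' @export
cropRoi <- function(set, roiMask) {
    stopifnot(is(set, "ChannelSet"), is(roiMask, "BinaryMask"))
    stopIfIncongruent(set, roiMask, "ROI mask and channel set")
    keep <- maskArray(roiMask)
    chans <- lapply(channelNames(set), function(nm) {
        a <- intensities(set[[nm]])
        a[!keep] <- 0L
        voxelStack(a, geometry(set), nm)
    })
    names(chans) <- channelNames(set)
    channelSet(chans)
}

#' Zero a stack inside a manually drawn region
#'
#' Subtracts a traced region from a stack by zeroing intensities inside
#' it, so that applying a JO-A territory mask and then subtracting it
#' yields the JO-B complement image.  \code{cropRoi} on a single channel
#' and \code{subtractMaskRegion} are voxelwise complementary: their sum
#' reconstructs the input.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param region a congruent \linkS4class{BinaryMask}.
#' @return a \linkS4class{VoxelStack} zeroed inside \code{region}.
#' @export
subtractMaskRegion <- function(stack, region) {
    stopifnot(is(stack, "VoxelStack"), is(region, "BinaryMask"))
    stopIfIncongruent(stack, region, "region mask and stack")
    a <- intensities(stack)
    a[maskArray(region)] <- 0L
    voxelStack(a, geometry(stack), channelName(stack))
}

#' Read a specimen manifest
#'
#' The manifest is a CSV with one row per specimen: \code{specimen_id},
#' \code{group}, calibration columns \code{dx}, \code{dy}, \code{dz},
#' \code{ap_axis}, \code{medial_direction}, one \code{channel_<Name>}
#' column per channel holding a TIFF path, and optional mask columns
#' \code{mask_roi}, \code{mask_JOA}, \code{mask_JOB}.  Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return a validated data.frame with an attribute \code{"channels"}
#'   listing the channel names present.
#' @export
readManifest <- function(path) {
    m <- read.csv(path, stringsAsFactors = FALSE)
    req <- c("specimen_id", "group", "dx", "dy", "dz", "ap_axis",
             "medial_direction")
    missing <- setdiff(req, names(m))
    if (length(missing))
        stop(sprintf("manifest lacks column(s): %s",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(m$specimen_id))
        stop("duplicate specimen_id in manifest")
    if (any(m$dx <= 0 | m$dy <= 0 | m$dz <= 0))
        stop("voxel pitches must be positive")
    chcols <- grep("^channel_", names(m), value = TRUE)
    if (!length(chcols)) stop("manifest has no channel_* columns")
    base <- dirname(normalizePath(path))
    for (cc in c(chcols, grep("^mask_", names(m), value = TRUE))) {
        rel <- nzchar(m[[cc]]) & !grepl("^(/|[A-Za-z]:)", m[[cc]])
        m[[cc]][rel] <- file.path(base, m[[cc]][rel])
    }
    attr(m, "channels") <- sub("^channel_", "", chcols)
    m
}
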