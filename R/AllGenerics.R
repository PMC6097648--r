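#' @rdname VoxelStack-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VoxelGeometry-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname VoxelStack-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname ChannelSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("level", function(x) standardGeneric("level"))

#' @rdname SliceProfile-class
#' @export
setGeneric("sliceAreas", function(x) standardGeneric("sliceAreas"))

#' @rdname SliceProfile-class
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' @rdname QuantSummary-class
#' @export
setGeneric("measures", function(x) standardGeneric("measures"))
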