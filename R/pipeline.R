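## End-to-end orchestration: filter -> threshold -> quantify for one
## specimen, and quantify-all -> group statistics for a study.

#' Pipeline configuration
#'
#' Houses every named constant of the analysis: the per-channel
#' threshold method map (Brp: intermodes on the top-hat-filtered
#' signal; GF/DA488 and NB: IsoData default; ShB: Renyi entropy), the
#' top-hat disc radius (3 px), the medial boundary (5 um, i.e. 23
#' pixels at 0.22 um), the Neurobiotin window (10 um), and the
#' rescale-after-top-hat flag.
#'
#' @slot methodMap named character: channel -> threshold method
#'   (\code{"intermodes"}, \code{"default"}, \code{"renyi"}).
#' @slot tophatRadius top-hat disc radius, pixels.
#' @slot boundaryUm medial boundary, um.
#' @slot nbWindowUm NB window length, um.
#' @slot rescaleAfterTophat logical flag.
#' @slot measures measures to compute, or \code{"auto"} for all whose
#'   channels are present.
#'
#' @param methodMap,tophatRadius,boundaryUm,nbWindowUm,rescaleAfterTophat,measures
#'   see slots.
#' @return \code{pipelineConfig} returns a \code{PipelineConfig}.
#' @export pipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(methodMap = "character", tophatRadius = "integer",
                   boundaryUm = "numeric", nbWindowUm = "numeric",
                   rescaleAfterTophat = "logical", measures = "character"),
    validity = function(object) {
        if (!all(object@methodMap %in% c("intermodes", "default", "renyi")))
            return("methods must be intermodes, default or renyi")
        if (object@tophatRadius < 1L) return("tophatRadius must be >= 1")
        if (object@boundaryUm <= 0 || object@nbWindowUm <= 0)
            return("boundaryUm and nbWindowUm must be positive")
        TRUE
    })

knownMeasures <- c("azOnGfVolume", "gfSurfaceArea", "medialSurfaceArea",
                   "azOnMedialVolume", "nbCouplingArea", "colocalization")

#' @rdname PipelineConfig-class
pipelineConfig <- function(methodMap = c(Brp = "intermodes", GF = "default",
                                         NB = "default", ShB = "renyi",
                                         nc82 = "intermodes"),
                           tophatRadius = 3L, boundaryUm = 5,
                           nbWindowUm = 10, rescaleAfterTophat = TRUE,
                           measures = "auto") {
    if (!identical(measures, "auto")) {
        bad <- setdiff(measures, knownMeasures)
        if (length(bad))
            stop(sprintf("unknown measure(s): %s; known: %s",
                         paste(bad, collapse = ", "),
                         paste(knownMeasures, collapse = ", ")))
    }
    new("PipelineConfig", methodMap = methodMap,
        tophatRadius = as.integer(tophatRadius), boundaryUm = boundaryUm,
        nbWindowUm = nbWindowUm, rescaleAfterTophat = rescaleAfterTophat,
        measures = measures)
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:\n  methods: ",
        paste(sprintf("%s=%s", names(object@methodMap), object@methodMap),
              collapse = ", "), "\n", sep = "")
    cat(sprintf("  tophat radius %d px, boundary %g um, NB window %g um, rescale %s\n",
                object@tophatRadius, object@boundaryUm, object@nbWindowUm,
                object@rescaleAfterTophat))
})

#' Read a pipeline configuration from JSON
#'
#' Versioned JSON schema; unknown keys are hard errors so that a typo
#' in a method name can never silently change an analysis.
#'
#' @param path JSON file path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    known <- c("version", "methodMap", "tophatRadius", "boundaryUm",
               "nbWindowUm", "rescaleAfterTophat", "measures")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
    cfg$version <- NULL
    do.call(pipelineConfig, cfg)
}

thresholdFor <- function(cfg, channel, stack) {
    m <- cfg@methodMap[[channel]]
    if (is.null(m) || is.na(m))
        stop(sprintf("no threshold method configured for channel '%s'",
                     channel))
    autoThreshold(stack, m)
}

#' Quantify one specimen
#'
#' Runs the full per-specimen analysis: optional ROI crop, top-hat
#' agglomeration removal on the Brp channel, per-channel pooled
#' stack-histogram thresholding and binarization, then every requested
#' measure whose channels are present: active-zone-on-GF overlap
#' volume, GF surface-area proxy, medial partition measures,
#' Neurobiotin coupling area, and per-region ShakB/Brp colocalization.
#' Threshold levels and mask voxel counts are returned in the
#' \code{"log"} attribute.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param channels a \linkS4class{ChannelSet} (channels among GF, NB,
#'   Brp, ShB; names must match \code{config@methodMap} entries).
#' @param roiMask optional \linkS4class{BinaryMask} ROI crop.
#' @param regions optional named list of \linkS4class{BinaryMask}
#'   region masks (e.g. JOA, JOB) for colocalization.
#' @param specimenId identifier for the output row.
#' @return a \linkS4class{QuantSummary} with attribute \code{"log"}.
#' @export
runSpecimen <- function(config, channels, roiMask = NULL, regions = NULL,
                        specimenId = "specimen") {
    stopifnot(is(config, "PipelineConfig"), is(channels, "ChannelSet"))
    if (!is.null(roiMask)) channels <- cropRoi(channels, roiMask)
    have <- channelNames(channels)
    wanted <- if (identical(config@measures, "auto")) knownMeasures
              else config@measures
    needs <- list(azOnGfVolume = c("Brp", "GF"),
                  gfSurfaceArea = "GF",
                  medialSurfaceArea = "GF",
                  azOnMedialVolume = c("Brp", "GF"),
                  nbCouplingArea = c("NB", "GF"),
                  colocalization = c("ShB", "Brp"))
    computable <- names(needs)[vapply(needs, function(nn)
        all(nn %in% have), logical(1))]
    if (!"colocalization" %in% wanted || is.null(regions))
        computable <- setdiff(computable, "colocalization")
    if (!identical(config@measures, "auto")) {
        missing <- setdiff(wanted, computable)
        if (length(missing))
            stop(sprintf("cannot compute %s (missing channels); computable: %s",
                         paste(missing, collapse = ", "),
                         paste(computable, collapse = ", ")),
                 call. = FALSE)
    }
    todo <- intersect(wanted, computable)

    log <- list(specimenId = specimenId)
    masks <- list()
    for (ch in intersect(c("GF", "NB", "Brp", "ShB"), have)) {
        stack <- channels[[ch]]
        if (ch == "Brp")
            stack <- removeAgglomerations(stack, config@tophatRadius,
                                          rescale = config@rescaleAfterTophat)
        th <- thresholdFor(config, ch, stack)
        masks[[ch]] <- binarize(stack, th)
        log[[paste0("level_", ch)]] <- level(th)
        log[[paste0("voxels_", ch)]] <- sum(maskArray(masks[[ch]]))
    }

    m <- c()
    if ("azOnGfVolume" %in% todo)
        m["azOnGfVolume"] <- overlapVolume(masks$Brp, masks$GF)
    if ("gfSurfaceArea" %in% todo)
        m["gfSurfaceArea"] <- surfaceAreaProxy(masks$GF)
    if (any(c("medialSurfaceArea", "azOnMedialVolume") %in% todo)) {
        part <- partitionMedial(masks$GF, config@boundaryUm)
        log$medialCenterIndex <- part$centerIndex
        log$medialOffsetPixels <- part$offsetPixels
        if ("medialSurfaceArea" %in% todo)
            m["medialSurfaceArea"] <- surfaceAreaProxy(part$medial)
        if ("azOnMedialVolume" %in% todo)
            m["azOnMedialVolume"] <- overlapVolume(masks$Brp, part$medial)
    }
    if ("nbCouplingArea" %in% todo)
        m["nbCouplingArea"] <- nbCouplingArea(masks$NB, masks$GF,
                                              config@nbWindowUm)
    regionTable <- emptyRegionTable()
    if ("colocalization" %in% todo)
        regionTable <- colocalization(masks$ShB, masks$Brp, regions)

    out <- quantSummary(specimenId, m, regionTable)
    attr(out, "log") <- log
    out
}

## Resolve one manifest row into runSpecimen inputs.
loadManifestRow <- function(row, chNames) {
    g <- voxelGeometry(dx = row$dx, dy = row$dy, dz = row$dz,
                       apAxis = row$ap_axis,
                       medialDirection = row$medial_direction)
    paths <- vapply(chNames, function(nm) row[[paste0("channel_", nm)]],
                    character(1))
    names(paths) <- chNames
    channels <- readChannelSet(paths, geometry = g)
    regions <- NULL
    if (!is.null(row$mask_JOA) && !is.na(row$mask_JOA) &&
        nzchar(row$mask_JOA)) {
        regions <- list(JOA = readMask(row$mask_JOA, g),
                        JOB = readMask(row$mask_JOB, g))
    }
    roi <- NULL
    if (!is.null(row$mask_roi) && !is.na(row$mask_roi) &&
        nzchar(row$mask_roi))
        roi <- readMask(row$mask_roi, g)
    list(channels = channels, regions = regions, roi = roi)
}

#' Run a full group study
#'
#' Quantifies every specimen of a study and compares the groups:
#' per-specimen \linkS4class{QuantSummary} rows, then ANOVA + Tukey HSD
#' over every measure.  The study may be an in-memory
#' \code{"PhantomStudy"} from [generateGroupStudy()] (region masks are
#' taken from its ground truth) or a manifest CSV path as read by
#' [readManifest()].
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param study a \code{"PhantomStudy"} or a manifest CSV path.
#' @param resultsCsv,reportJson optional output paths.
#' @return list with \code{results} (data.frame, one row per specimen)
#'   and \code{reports} (named list of \linkS4class{StatsReport}).
#' @export
runStudy <- function(config, study, resultsCsv = NULL, reportJson = NULL) {
    stopifnot(is(config, "PipelineConfig"))
    rows <- list()
    if (inherits(study, "PhantomStudy")) {
        man <- study$manifest
        if (anyDuplicated(man$specimen_id))
            stop("duplicate specimen_id in study")
        for (i in seq_len(nrow(man))) {
            sid <- man$specimen_id[i]
            sp <- study$specimens[[sid]]
            regions <- list(JOA = sp$truth@masks$joA,
                            JOB = sp$truth@masks$joB)
            qs <- runSpecimen(config, sp$channels, regions = regions,
                              specimenId = sid)
            r <- as.data.frame(qs)
            r$group <- man$group[i]
            rows[[sid]] <- r
        }
    } else {
        man <- readManifest(study)
        chNames <- attr(man, "channels")
        for (i in seq_len(nrow(man))) {
            sid <- man$specimen_id[i]
            inp <- loadManifestRow(man[i, ], chNames)
            qs <- runSpecimen(config, inp$channels, roiMask = inp$roi,
                              regions = inp$regions, specimenId = sid)
            r <- as.data.frame(qs)
            r$group <- man$group[i]
            rows[[sid]] <- r
        }
    }
    results <- do.call(rbind, rows)
    rownames(results) <- NULL
    tab <- groupTable(results)
    reports <- list()
    for (msr in unique(tab$measure)) {
        rep <- tryCatch(anovaTukey(tab, msr), error = function(e) NULL)
        if (!is.null(rep)) reports[[msr]] <- rep
    }
    if (!is.null(resultsCsv)) write.csv(results, resultsCsv,
                                        row.names = FALSE)
    if (!is.null(reportJson))
        jsonlite::write_json(lapply(reports, statsReportAsList),
                             reportJson, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    list(results = results, reports = reports)
}
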