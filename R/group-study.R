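## Synthetic multi-group studies: n specimens per genotype-like group,
## each a phantom whose construction parameters are the base spec scaled
## by the group's effect multipliers and by specimen-level lognormal
## variability.  One master seed deterministically derives every
## specimen's child seed.

effectDims <- c("jobPlaqueVolume", "nbAxonCount", "medialBranchLength",
                "azCount")

#' Preset group effects emulating the four genotype-like conditions
#'
#' Four groups: a control; an N+16-like group with a 4-fold increase of
#' gap-junction plaque volume in the JO-B territory and increased
#' coupled-axon count; an N-like group with near-abolished dye coupling
#' (multiplier 0.15; the generator contract requires strictly positive
#' multipliers) and modestly reduced branching; and an En-like positive
#' control with more active zones, longer medial branches and increased
#' coupling.
#'
#' @return named list of multiplier vectors, one per group.
#' @export
defaultGroupEffects <- function() {
    list(
        control = c(jobPlaqueVolume = 1, nbAxonCount = 1,
                    medialBranchLength = 1, azCount = 1),
        shakB_N16 = c(jobPlaqueVolume = 4, nbAxonCount = 1.8,
                      medialBranchLength = 1, azCount = 1),
        shakB_N = c(jobPlaqueVolume = 1, nbAxonCount = 0.15,
                    medialBranchLength = 0.9, azCount = 1),
        en = c(jobPlaqueVolume = 1, nbAxonCount = 1.7,
               medialBranchLength = 1.5, azCount = 2.4))
}

applyEffects <- function(base, eff) {
    spec <- base
    spec@plaqueCountB <- max(1L, as.integer(roundHalfUp(
        base@plaqueCountB * eff[["jobPlaqueVolume"]])))
    spec@nbAxonCount <- as.integer(roundHalfUp(
        base@nbAxonCount * eff[["nbAxonCount"]]))
    spec@branchLengthsUm <- base@branchLengthsUm *
        eff[["medialBranchLength"]]
    spec@azCount <- max(0L, as.integer(roundHalfUp(
        base@azCount * eff[["azCount"]])))
    spec
}

#' Generate a synthetic group study
#'
#' Emits \code{nPerGroup} phantom specimens per group.  Group effects
#' are multipliers on four construction parameters: ShakB plaque volume
#' in the JO-B territory (via plaque count), Neurobiotin-coupled axon
#' count, medial branch length, and active-zone count.  Each specimen
#' additionally draws independent lognormal variability (sdlog
#' \code{sdLog}) on each of the four dimensions around its group mean.
#' All randomness derives deterministically from \code{seed}.
#'
#' @param base a \linkS4class{PhantomSpec}; per-specimen specs are
#'   derived from it.
#' @param groupEffects named list of multiplier vectors over
#'   \code{c("jobPlaqueVolume", "nbAxonCount", "medialBranchLength",
#'   "azCount")}; missing entries default to 1.  All multipliers must
#'   be strictly positive.
#' @param nPerGroup specimens per group (>= 2).
#' @param seed master seed.
#' @param sdLog lognormal specimen-level sdlog (default 0.15; draws are
#'   truncated at two sd so scenes stay inside the field).
#' @param dir if non-NULL, write per-specimen channel TIFFs, region
#'   mask TIFFs and a stack-IO-compatible \code{manifest.csv} there.
#' @return a list of class \code{"PhantomStudy"} with elements
#'   \code{manifest} (data.frame: specimen_id, group, seed, effective
#'   multipliers), \code{specimens} (named list of
#'   \code{generatePhantom} results) and \code{dir}.
#' @export
generateGroupStudy <- function(base, groupEffects = defaultGroupEffects(),
                               nPerGroup = 8L, seed = 1L, sdLog = 0.15,
                               dir = NULL) {
    stopifnot(is(base, "PhantomSpec"))
    if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
    if (is.null(names(groupEffects)) || any(!nzchar(names(groupEffects))))
        stop("groupEffects must be a named list")
    groupEffects <- lapply(groupEffects, function(e) {
        full <- c(jobPlaqueVolume = 1, nbAxonCount = 1,
                  medialBranchLength = 1, azCount = 1)
        full[names(e)] <- e
        if (any(full <= 0))
            stop("invalid multiplier (<= 0) in groupEffects", call. = FALSE)
        full
    })
    set.seed(seed)
    specimens <- list()
    rows <- list()
    idx <- 0L
    for (grp in names(groupEffects)) {
        for (i in seq_len(nPerGroup)) {
            idx <- idx + 1L
            childSeed <- as.integer((seed + 104729 * idx) %% 2147483647L)
            set.seed(childSeed)
            ## lognormal biological variability, truncated at +/- 2 sd
            ## so every specimen's scene stays inside the field of view
            z <- pmin(pmax(rnorm(length(effectDims), 0, sdLog),
                           -2 * sdLog), 2 * sdLog)
            noise <- exp(z)
            names(noise) <- effectDims
            eff <- groupEffects[[grp]] * noise
            spec <- applyEffects(base, eff)
            spec@seed <- childSeed
            sid <- sprintf("%s_%02d", grp, i)
            specimens[[sid]] <- generatePhantom(spec)
            rows[[sid]] <- data.frame(
                specimen_id = sid, group = grp, seed = childSeed,
                jobPlaqueVolume = eff[["jobPlaqueVolume"]],
                nbAxonCount = eff[["nbAxonCount"]],
                medialBranchLength = eff[["medialBranchLength"]],
                azCount = eff[["azCount"]], stringsAsFactors = FALSE)
        }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    study <- structure(list(manifest = manifest, specimens = specimens,
                            base = base, dir = dir),
                       class = "PhantomStudy")
    if (!is.null(dir)) writeStudy(study, dir)
    study
}

#' @export
print.PhantomStudy <- function(x, ...) {
    cat(sprintf("PhantomStudy: %d specimens, %d group(s) [%s]\n",
                nrow(x$manifest), length(unique(x$manifest$group)),
                paste(unique(x$manifest$group), collapse = ", ")))
    invisible(x)
}

## Write a study to disk as per-channel TIFFs + region masks + manifest.
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- geometry(study$specimens[[1]]$channels)
    man <- study$manifest
    chNames <- channelNames(study$specimens[[1]]$channels)
    for (nm in chNames) man[[paste0("channel_", nm)]] <- NA_character_
    man$mask_JOA <- NA_character_
    man$mask_JOB <- NA_character_
    man$dx <- g@dx; man$dy <- g@dy; man$dz <- g@dz
    man$ap_axis <- g@apAxis; man$medial_direction <- g@medialDirection
    for (i in seq_len(nrow(man))) {
        sid <- man$specimen_id[i]
        sp <- study$specimens[[sid]]
        paths <- file.path(dir, sprintf("%s_%s.tif", sid, chNames))
        names(paths) <- chNames
        writeChannelSet(sp$channels, paths)
        man[i, paste0("channel_", chNames)] <- basename(paths)
        pA <- file.path(dir, sprintf("%s_maskJOA.tif", sid))
        pB <- file.path(dir, sprintf("%s_maskJOB.tif", sid))
        writeMask(sp$truth@masks$joA, pA)
        writeMask(sp$truth@masks$joB, pB)
        man$mask_JOA[i] <- basename(pA)
        man$mask_JOB[i] <- basename(pB)
    }
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    invisible(file.path(dir, "manifest.csv"))
}
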