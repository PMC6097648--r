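## Pooled stack-histogram auto-thresholding.  Three methods are
## provided, matching the per-channel map used for quantification:
## Intermodes (Brp), the classic iterated-intermeans "Default" IsoData
## variant (DA488/NB), and Renyi entropy (ShakB).  Foreground is always
## intensity strictly greater than the returned level.

#' Pooled stack histogram
#'
#' One 256-bin histogram pooled over all slices of an 8-bit stack.
#' With \code{ignoreWhite} (the default, matching the pipeline's
#' "Ignore white" setting) bin 255 is zeroed and its count recorded as
#' excluded, so saturated voxels never drive the threshold.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param ignoreWhite exclude bin 255? default TRUE.
#' @return an \linkS4class{IntensityHistogram}.
#' @export
stackHistogram <- function(stack, ignoreWhite = TRUE) {
    stopifnot(is(stack, "VoxelStack"))
    counts <- tabulate(as.integer(intensities(stack)) + 1L, 256L)
    excluded <- 0
    if (ignoreWhite) {
        excluded <- counts[256L]
        counts[256L] <- 0L
    }
    intensityHistogram(counts, ignoreWhite = ignoreWhite,
                       sourceVoxels = length(intensities(stack)),
                       excludedWhite = excluded)
}

## 3-point running-mean smoothing with mirror-reflected ends
## (h[-1] := h[1], h[256] := h[254]).
smoothHistogram3 <- function(h) {
    n <- length(h)
    left <- c(h[2L], h[-n])
    right <- c(h[-1L], h[n - 1L])
    (left + h + right) / 3
}

## Strict local maxima (plateaus excluded); smoothing resolves plateaus
## into strict peaks within a couple of passes.
localMaxima <- function(h) {
    n <- length(h)
    which(h > c(-Inf, h[-n]) & h > c(h[-1L], -Inf))
}

#' Intermodes threshold
#'
#' Iteratively smooths the histogram with a 3-bin running mean until
#' exactly two local maxima remain, then takes the floor of their
#' midpoint.  Errors if the histogram cannot be reduced to two modes
#' within the iteration cap.
#'
#' @param hist an \linkS4class{IntensityHistogram}.
#' @param maxIter smoothing-pass cap; default 10000.
#' @return a \linkS4class{ThresholdResult} with the surviving mode pair
#'   in \code{diagnostics}.
#' @export
thresholdIntermodes <- function(hist, maxIter = 10000L) {
    stopifnot(is(hist, "IntensityHistogram"))
    h <- as.numeric(hist@counts)
    if (sum(h) == 0) stop("empty histogram")
    iter <- 0L
    repeat {
        peaks <- localMaxima(h)
        if (length(peaks) == 2L) break
        if (iter >= maxIter)
            stop("histogram cannot be bimodalized", call. = FALSE)
        h <- smoothHistogram3(h)
        iter <- iter + 1L
    }
    j <- peaks[1L] - 1L   # back to 0-based intensity levels
    k <- peaks[2L] - 1L
    thresholdResult(floor((j + k) / 2), "intermodes", iter,
                    diagnostics = list(modes = c(j, k)))
}

#' IsoData ("Default") threshold
#'
#' The iterated-intermeans fixed point in the variant of the original
#' ImageJ default routine: bins 0 and 255 are zeroed first (so erased
#' areas and saturation never count), then starting from the midpoint of
#' the nonzero support the level is updated to
#' \code{floor((mean below or at t + mean above t) / 2)} until stable.
#' The floor map is monotone, so the iteration terminates without
#' cycling.  A histogram whose trimmed mass sits in a single bin returns
#' that bin.
#'
#' @param hist an \linkS4class{IntensityHistogram}.
#' @return a \linkS4class{ThresholdResult}.
#' @export
thresholdIsoData <- function(hist) {
    stopifnot(is(hist, "IntensityHistogram"))
    h <- as.numeric(hist@counts)
    h[c(1L, 256L)] <- 0      # trim extreme bins (erased areas, saturation)
    if (sum(h) == 0) stop("empty histogram (after trimming bins 0 and 255)")
    lev <- 0:255
    nz <- which(h > 0) - 1L
    lo <- min(nz); hi <- max(nz)
    if (lo == hi)
        return(thresholdResult(lo, "default_isodata", 0L))
    t <- floor((lo + hi) / 2)
    iter <- 0L
    repeat {
        below <- lev <= t
        mu1 <- sum(lev[below] * h[below]) / sum(h[below])
        mu2 <- sum(lev[!below] * h[!below]) / sum(h[!below])
        tNew <- floor((mu1 + mu2) / 2)
        iter <- iter + 1L
        if (tNew == t || iter > 256L) break
        t <- tNew
    }
    thresholdResult(t, "default_isodata", iter)
}

## Renyi entropy criterion of one order for every candidate split t
## (background = bins 0..t).  Follows the classic plugin semantics:
## candidates range over the nonzero support; at the top of the support
## the foreground class is empty, which for the Shannon order
## contributes zero entropy and for the other orders invalidates the
## criterion (value 0, never selected).  Returns a 256-vector; invalid
## splits are -Inf.
renyiCriterion <- function(p, alpha) {
    n <- length(p)
    P1 <- cumsum(p)
    P2 <- 1 - P1
    nz <- which(p > 0)
    first <- nz[1L]
    last <- nz[length(nz)]
    out <- rep(-Inf, n)
    idx <- first:last
    if (abs(alpha - 1) < 1e-12) {
        plogp <- ifelse(p > 0, p * log(p), 0)
        C1 <- cumsum(plogp)
        Ctot <- C1[n]
        entBack <- -C1 / P1 + log(P1)
        entObj <- rep(0, n)
        inner <- idx[idx < last]
        entObj[inner] <- -(Ctot - C1[inner]) / P2[inner] + log(P2[inner])
        out[idx] <- entBack[idx] + entObj[idx]
    } else {
        pa <- p^alpha
        A1 <- cumsum(pa)
        Atot <- A1[n]
        term <- 1 / (1 - alpha)
        inner <- idx[idx < last]
        prod <- (A1[inner] / P1[inner]^alpha) *
                ((Atot - A1[inner]) / P2[inner]^alpha)
        out[inner] <- ifelse(prod > 0, term * log(prod), 0)
        out[last] <- 0   # empty foreground: criterion undefined, scored 0
    }
    out
}

## Plugin argmax convention: the lowest level attaining the maximum,
## provided the maximum is positive; otherwise level 0.
renyiCandidate <- function(crit) {
    m <- max(crit)
    if (m > 0) which.max(crit) - 1L else 0L
}

#' Renyi-entropy threshold
#'
#' Computes the candidate level maximizing the summed foreground and
#' background Renyi entropies at orders 1/2, 1 (Shannon) and 2, then
#' combines the three sorted candidates with the weighting rule of
#' Sahoo, Wilkins and Yeager (1997): weights (1,2,1) when the sorted
#' candidates are mutually within 5 levels, (0,1,3) when only the lower
#' pair is close, (3,1,0) when only the upper pair is close, and
#' (1,2,1) otherwise; the final level mixes the candidates by the
#' cumulative mass between the extreme candidates.  Ties in each argmax
#' go to the lowest level.
#'
#' @param hist an \linkS4class{IntensityHistogram}; needs at least two
#'   nonzero bins.
#' @return a \linkS4class{ThresholdResult}; \code{diagnostics$tStars}
#'   holds the per-order candidates (orders 1/2, 1, 2, unsorted).
#' @export
thresholdRenyiEntropy <- function(hist) {
    stopifnot(is(hist, "IntensityHistogram"))
    h <- as.numeric(hist@counts)
    if (sum(h > 0) < 2L)
        stop("Renyi entropy threshold needs at least 2 nonzero histogram bins")
    p <- h / sum(h)
    tStar <- vapply(c(0.5, 1, 2), function(alpha) {
        renyiCandidate(renyiCriterion(p, alpha))
    }, integer(1))
    ts <- sort(tStar)
    t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
    if (abs(t1 - t2) <= 5) {
        if (abs(t2 - t3) <= 5) b <- c(1, 2, 1) else b <- c(0, 1, 3)
    } else {
        if (abs(t2 - t3) <= 5) b <- c(3, 1, 0) else b <- c(1, 2, 1)
    }
    P1 <- cumsum(p)
    omega <- P1[t3 + 1L] - P1[t1 + 1L]
    lvl <- floor(t1 * (P1[t1 + 1L] + 0.25 * omega * b[1]) +
                 0.25 * t2 * omega * b[2] +
                 t3 * ((1 - P1[t3 + 1L]) + 0.25 * omega * b[3]))
    thresholdResult(lvl, "renyi_entropy",
                    diagnostics = list(tStars = tStar, weights = b))
}

#' Auto-threshold a stack by name
#'
#' Convenience dispatcher over the three methods, using the pooled
#' stack histogram ([stackHistogram()]).
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param method \code{"intermodes"}, \code{"default"} (IsoData) or
#'   \code{"renyi"}.
#' @param ignoreWhite passed to [stackHistogram()].
#' @return a \linkS4class{ThresholdResult}.
#' @export
autoThreshold <- function(stack, method = c("intermodes", "default", "renyi"),
                          ignoreWhite = TRUE) {
    method <- match.arg(method)
    hist <- stackHistogram(stack, ignoreWhite = ignoreWhite)
    switch(method,
           intermodes = thresholdIntermodes(hist),
           default = thresholdIsoData(hist),
           renyi = thresholdRenyiEntropy(hist))
}

#' Binarize a stack at a threshold level
#'
#' Foreground is intensity strictly greater than \code{level}.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param level integer in 0..255, or a \linkS4class{ThresholdResult}.
#' @return a \linkS4class{BinaryMask}.
#' @export
binarize <- function(stack, level) {
    stopifnot(is(stack, "VoxelStack"))
    if (is(level, "ThresholdResult")) level <- level@level
    if (length(level) != 1L || is.na(level) || level < 0 || level > 255)
        stop("level must be a single integer in [0, 255]")
    binaryMask(intensities(stack) > level, geometry(stack))
}
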