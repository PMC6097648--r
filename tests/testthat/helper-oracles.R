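# Independent brute-force oracles and fixture builders.  Everything here
# is deliberately written as plain loops, separate from the package's
# vectorized/C++ implementations.

mkGeom <- function(dx = 0.22, dy = dx, dz = 1, apAxis = 3L, medialDir = 1L) {
    voxelGeometry(dx = dx, dy = dy, dz = dz, apAxis = apAxis,
                  medialDirection = medialDir)
}

mkStack <- function(arr, g = mkGeom(), name = "chan") {
    voxelStack(array(as.integer(arr), dim(arr)), g, name)
}

mkMask <- function(arr, g = mkGeom()) {
    binaryMask(array(as.logical(arr), dim(arr)), g)
}

randomStack <- function(dims, g = mkGeom(), max = 255L) {
    mkStack(array(sample.int(max + 1L, prod(dims), replace = TRUE) - 1L,
                  dims), g)
}

randomMask <- function(dims, g = mkGeom(), p = 0.3) {
    mkMask(array(runif(prod(dims)) < p, dims), g)
}

# Disc footprint by the pinned definition (radius 1 = full 3x3).
oracleDisc <- function(radius) {
    if (radius == 1) {
        off <- expand.grid(dr = -1:1, dc = -1:1)
    } else {
        off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
        off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, ]
    }
    off
}

# Per-pixel neighbourhood min/max with edge replication, one 2D slice.
oracleRank2D <- function(m, radius, mode) {
    off <- oracleDisc(radius)
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    for (r in seq_len(nr)) {
        for (c in seq_len(nc)) {
            vals <- numeric(nrow(off))
            for (k in seq_len(nrow(off))) {
                rr <- min(max(r + off$dr[k], 1L), nr)
                cc <- min(max(c + off$dc[k], 1L), nc)
                vals[k] <- m[rr, cc]
            }
            out[r, c] <- as.integer(
                if (mode == "min") min(vals) else max(vals))
        }
    }
    out
}

# Iterated 3-point smoothing (mirror ends) until exactly two strict
# local maxima; returns floor of the mode midpoint, or NA.
oracleIntermodes <- function(counts, cap = 10000L) {
    h <- as.numeric(counts)
    n <- length(h)
    nPeaks <- function(v) {
        k <- 0L
        for (i in seq_len(n)) {
            left <- if (i == 1L) -Inf else v[i - 1L]
            right <- if (i == n) -Inf else v[i + 1L]
            if (v[i] > left && v[i] > right) k <- k + 1L
        }
        k
    }
    iter <- 0L
    while (nPeaks(h) != 2L) {
        if (iter >= cap) return(NA_integer_)
        h2 <- h
        for (i in seq_len(n)) {
            lo <- if (i == 1L) h[2L] else h[i - 1L]
            hi <- if (i == n) h[n - 1L] else h[i + 1L]
            h2[i] <- (lo + h[i] + hi) / 3
        }
        h <- h2
        iter <- iter + 1L
    }
    peaks <- c()
    for (i in seq_len(n)) {
        left <- if (i == 1L) -Inf else h[i - 1L]
        right <- if (i == n) -Inf else h[i + 1L]
        if (h[i] > left && h[i] > right) peaks <- c(peaks, i - 1L)
    }
    floor((peaks[1] + peaks[2]) / 2)
}

# Iterated intermeans fixed point after trimming bins 0 and 255,
# started at the midpoint of the nonzero support, floor update.
oracleIsoData <- function(counts) {
    h <- as.numeric(counts)
    h[1] <- 0; h[256] <- 0
    lev <- 0:255
    nz <- lev[h > 0]
    if (length(nz) == 0) return(NA_integer_)
    if (length(nz) == 1) return(nz)
    t <- floor((min(nz) + max(nz)) / 2)
    for (i in 1:500) {
        s1 <- 0; w1 <- 0; s2 <- 0; w2 <- 0
        for (v in 0:255) {
            if (v <= t) { s1 <- s1 + v * h[v + 1]; w1 <- w1 + h[v + 1] }
            else { s2 <- s2 + v * h[v + 1]; w2 <- w2 + h[v + 1] }
        }
        tNew <- floor((s1 / w1 + s2 / w2) / 2)
        if (tNew == t) return(t)
        t <- tNew
    }
    t
}

# Exhaustive-split Renyi entropy candidate of one order, plugin
# conventions: candidates over the nonzero support; at the top of the
# support the foreground is empty (Shannon order scores background
# entropy only, other orders score 0); the candidate is the lowest
# argmax provided the maximum is positive, else 0.
oracleRenyiCandidate <- function(counts, alpha) {
    p <- as.numeric(counts) / sum(counts)
    nz <- which(p > 0)
    first <- nz[1]; last <- nz[length(nz)]
    best <- 0; bestT <- 0L
    for (ti in first:last) {
        P1 <- sum(p[1:ti])
        P2 <- 1 - P1
        if (abs(alpha - 1) < 1e-12) {
            eb <- 0
            for (i in 1:ti) if (p[i] > 0)
                eb <- eb - (p[i] / P1) * log(p[i] / P1)
            eo <- 0
            if (ti < last) {
                for (i in (ti + 1):256) if (p[i] > 0)
                    eo <- eo - (p[i] / P2) * log(p[i] / P2)
            }
            tot <- eb + eo
        } else if (ti == last) {
            tot <- 0
        } else {
            eb <- sum((p[1:ti] / P1)^alpha)
            eo <- sum((p[(ti + 1):256] / P2)^alpha)
            tot <- if (eb * eo > 0) log(eb * eo) / (1 - alpha) else 0
        }
        if (tot > best) { best <- tot; bestT <- ti - 1L }
    }
    bestT
}

# Random histogram as a mixture of two separated rounded-gaussian bumps
# plus sparse noise: guaranteed bimodalizable, used for the Intermodes
# oracle comparisons.
randomBimodalHistogram <- function() {
    m1 <- sample(20:90, 1)
    m2 <- sample(140:230, 1)
    s1 <- runif(1, 3, 12)
    s2 <- runif(1, 3, 12)
    w <- runif(1, 0.25, 0.75)
    x <- 0:255
    h <- round(2e4 * (w * dnorm(x, m1, s1) + (1 - w) * dnorm(x, m2, s2)))
    h[256] <- 0
    intensityHistogram(as.integer(h), ignoreWhite = TRUE,
                       sourceVoxels = sum(h), excludedWhite = 0)
}

# General random sparse histogram (may be unimodal).
randomHistogram <- function(nBins = 40) {
    h <- integer(256)
    bins <- sample(2:250, nBins)
    h[bins] <- sample.int(5000L, nBins, replace = TRUE)
    intensityHistogram(h, ignoreWhite = TRUE, sourceVoxels = sum(h),
                       excludedWhite = 0)
}

# Small fast phantom spec for pipeline-level tests.
testPhantomSpec <- function(...) {
    phantomSpec(dims = c(96L, 96L, 48L), ...)
}
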