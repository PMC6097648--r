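test_that("pooled stack histograms account for every voxel", {
    g <- mkGeom()
    white <- mkStack(array(255L, c(4, 4, 3)), g)
    h <- stackHistogram(white, ignoreWhite = TRUE)
    expect_equal(sum(h@counts), 0L)
    expect_equal(h@excludedWhite, 48)

    a <- array(0L, c(4, 4, 3)); a[1:5] <- 7L
    h2 <- stackHistogram(mkStack(a, g))
    expect_equal(h2@counts[8L], 5L)   # bin index 8 is intensity 7

    ## pooled histogram equals the sum of per-slice histograms
    set.seed(3)
    st <- randomStack(c(6L, 6L, 4L), g, max = 254L)
    pooled <- stackHistogram(st)@counts
    perSlice <- Reduce(`+`, lapply(1:4, function(s)
        tabulate(intensities(st)[, , s] + 1L, 256L)))
    expect_equal(pooled, perSlice)
})

test_that("intermodes finds the midpoint of two surviving modes", {
    h <- integer(256)
    h[51] <- 1000L; h[151] <- 1000L     # intensities 50 and 150
    res <- thresholdIntermodes(intensityHistogram(h, sourceVoxels = 2000))
    expect_equal(level(res), 100L)
    expect_equal(res@diagnostics$modes, c(50, 150))

    ## symmetry about a centre bin is preserved by smoothing
    h2 <- integer(256)
    h2[81] <- 500L; h2[121] <- 500L     # symmetric about intensity 100
    expect_equal(level(thresholdIntermodes(
        intensityHistogram(h2, sourceVoxels = 1000))), 100L)

    h3 <- integer(256); h3[41] <- 999L
    expect_error(thresholdIntermodes(
        intensityHistogram(h3, sourceVoxels = 999)),
        "cannot be bimodalized")
})

test_that("intermodes matches the iterative-smoothing oracle", {
    set.seed(202)
    for (i in 1:50) {
        h <- randomBimodalHistogram()
        expect_equal(level(thresholdIntermodes(h)),
                     oracleIntermodes(h@counts), label = paste("draw", i))
    }
})

test_that("isodata default handles spikes and degenerate histograms", {
    h <- integer(256)
    h[41] <- 100L; h[201] <- 100L       # intensities 40 and 200
    res <- thresholdIsoData(intensityHistogram(h, sourceVoxels = 200))
    expect_equal(level(res), 120L)

    hb <- integer(256); hb[101] <- 50L  # all mass at intensity 100
    expect_equal(level(thresholdIsoData(
        intensityHistogram(hb, sourceVoxels = 50))), 100L)

    h0 <- integer(256)
    expect_error(thresholdIsoData(intensityHistogram(h0, sourceVoxels = 0)),
                 "empty")
})

test_that("isodata matches the independent fixed-point oracle", {
    set.seed(303)
    for (i in 1:50) {
        h <- randomHistogram(nBins = sample(5:80, 1))
        expect_equal(level(thresholdIsoData(h)), oracleIsoData(h@counts),
                     label = paste("draw", i))
    }
})

test_that("isodata is shift-equivariant on spike histograms", {
    for (shift in c(5L, 20L, 40L)) {
        h <- integer(256); h[31] <- 80L; h[151] <- 40L
        hs <- integer(256)
        hs[31 + shift] <- 80L; hs[151 + shift] <- 40L
        l0 <- level(thresholdIsoData(intensityHistogram(h,
                                                        sourceVoxels = 120)))
        l1 <- level(thresholdIsoData(intensityHistogram(hs,
                                                        sourceVoxels = 120)))
        expect_equal(l1, l0 + shift)
    }
})

test_that("renyi candidates match the exhaustive-split oracle", {
    set.seed(404)
    for (i in 1:20) {
        h <- randomHistogram(nBins = sample(5:80, 1))
        res <- thresholdRenyiEntropy(h)
        got <- res@diagnostics$tStars
        want <- vapply(c(0.5, 1, 2), function(a)
            oracleRenyiCandidate(h@counts, a), integer(1))
        expect_equal(got, want, label = paste("draw", i))
        ## the combined level is a convex mixture of the candidates
        expect_gte(level(res), min(got))
        expect_lte(level(res), max(got))
    }
})

test_that("renyi separates two spikes and rejects degenerate input", {
    h <- integer(256); h[11] <- 500L; h[201] <- 500L
    lvl <- level(thresholdRenyiEntropy(intensityHistogram(
        h, sourceVoxels = 1000)))
    expect_gt(lvl, 10)
    expect_lt(lvl, 200)

    h1 <- integer(256); h1[51] <- 10L
    expect_error(thresholdRenyiEntropy(intensityHistogram(
        h1, sourceVoxels = 10)), "2 nonzero")
    h0 <- integer(256)
    expect_error(thresholdRenyiEntropy(intensityHistogram(
        h0, sourceVoxels = 0)), "2 nonzero")
})

test_that("binarization is a strict threshold, monotone in the level", {
    g <- mkGeom()
    a <- array(c(100L, 101L, 0L, 255L), c(2, 2, 1))
    st <- mkStack(a, g)
    m <- maskArray(binarize(st, 100L))
    expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))
    expect_equal(sum(maskArray(binarize(st, 0L))), 3L)  # every nonzero voxel
    expect_equal(sum(maskArray(binarize(st, 255L))), 0L)
    expect_error(binarize(st, 300), "level")

    set.seed(6)
    st2 <- randomStack(c(8L, 8L, 2L), g)
    counts <- vapply(seq(0L, 255L, by = 15L), function(l)
        sum(maskArray(binarize(st2, l))), numeric(1))
    expect_true(all(diff(counts) <= 0))
})
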