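test_that("per-slice areas and total volume follow the calibration", {
    g <- mkGeom()                       # 0.22 x 0.22 x 1 um
    empty <- mkMask(array(FALSE, c(6, 6, 3)), g)
    expect_equal(sliceAreas(perSliceArea(empty)), rep(0, 3))

    a <- array(FALSE, c(6, 6, 3)); a[1:10 + 6] <- TRUE  # 10 voxels, slice 1
    prof <- perSliceArea(mkMask(a, g))
    expect_equal(sliceAreas(prof)[1], 10 * 0.22 * 0.22)   # 0.484 um^2
    expect_equal(totalVolume(prof), sum(sliceAreas(prof)) * 1)

    set.seed(21)
    m <- randomMask(c(7L, 7L, 4L), g, 0.3)
    prof2 <- perSliceArea(m)
    brute <- vapply(1:4, function(s) sum(maskArray(m)[, , s]),
                    numeric(1)) * 0.22^2
    expect_equal(sliceAreas(prof2), brute)
})

test_that("overlap volume is a symmetric bounded conjunction measure", {
    set.seed(22)
    g <- mkGeom()
    a <- randomMask(c(8L, 8L, 3L), g, 0.4)
    b <- randomMask(c(8L, 8L, 3L), g, 0.4)
    expect_equal(overlapVolume(a, a), maskVolume(a))
    brute <- sum(maskArray(a) & maskArray(b)) * 0.22^2 * 1
    expect_equal(overlapVolume(a, b), brute)
    expect_equal(overlapVolume(a, b), overlapVolume(b, a))
    expect_lte(overlapVolume(a, b), min(maskVolume(a), maskVolume(b)))

    d1 <- array(FALSE, c(2, 2, 2)); d1[1, 1, 1] <- TRUE
    d2 <- array(FALSE, c(2, 2, 2)); d2[2, 2, 2] <- TRUE
    expect_equal(overlapVolume(mkMask(d1, g), mkMask(d2, g)), 0)

    bad <- randomMask(c(8L, 8L, 4L), g)
    expect_error(overlapVolume(a, bad), "incongruent")
})

test_that("growing a mask never shrinks the overlap", {
    set.seed(23)
    g <- mkGeom()
    a <- randomMask(c(8L, 8L, 3L), g, 0.3)
    b <- randomMask(c(8L, 8L, 3L), g, 0.3)
    bigger <- binaryMask(maskArray(b) |
                         array(runif(192) < 0.2, c(8, 8, 3)), g)
    expect_gte(overlapVolume(a, bigger), overlapVolume(a, b))
})

test_that("surface-area proxy reproduces its closed forms", {
    gc <- mkGeom(dz = 0.22)             # cubic 0.22 um voxels
    one <- array(FALSE, c(5, 5, 1)); one[3, 3, 1] <- TRUE
    expect_equal(surfaceAreaProxy(mkMask(one, gc)), 0.22^3 / 0.22)  # 0.0484

    rect <- array(FALSE, c(9, 8, 1)); rect[3:7, 3:6, 1] <- TRUE
    expect_equal(surfaceAreaProxy(mkMask(rect, gc)), 14 * 0.22^3 / 0.22)

    empty <- mkMask(array(FALSE, c(4, 4, 2)), gc)
    expect_equal(surfaceAreaProxy(empty), 0)

    ## closed form for all rectangle sizes 3..20 in one slice
    for (a in c(3, 7, 12, 20)) {
        for (b in c(3, 9, 20)) {
            m <- array(FALSE, c(a + 4L, b + 4L, 1L))
            m[3:(a + 2), 3:(b + 2), 1] <- TRUE
            want <- (a * b - (a - 2) * (b - 2)) * 0.22^3 / 0.22
            expect_equal(surfaceAreaProxy(mkMask(m, gc)), want,
                         label = sprintf("%dx%d", a, b))
        }
    }
})

test_that("the medial boundary is 23 pixels at the published calibration", {
    g <- mkGeom()
    a <- array(FALSE, c(4, 60, 2)); a[2, 10:40, 1] <- TRUE
    part <- partitionMedial(mkMask(a, g), boundaryUm = 5)
    expect_equal(part$offsetPixels, 23)
})

test_that("medial partitioning is a disjoint exhaustive split", {
    set.seed(24)
    g <- mkGeom()
    for (rep in 1:5) {
        m <- randomMask(c(10L, 30L, 4L), g, 0.25)
        if (!any(maskArray(m))) next
        part <- partitionMedial(m, boundaryUm = 2)
        expect_false(any(maskArray(part$medial) & maskArray(part$core)))
        expect_identical(maskArray(part$medial) | maskArray(part$core),
                         maskArray(m))
    }
    ## a compact mask has no voxels 5 um beyond its own centre
    comp <- array(FALSE, c(6, 20, 2)); comp[2:4, 8:12, ] <- TRUE
    part <- partitionMedial(mkMask(comp, g), boundaryUm = 5)
    expect_equal(sum(maskArray(part$medial)), 0L)
    expect_error(partitionMedial(mkMask(array(FALSE, c(4, 4, 1)), g)),
                 "empty")
})

test_that("medial partitioning recovers constructed branch voxels", {
    ## a core blob at the centre plus a branch extending 10 um medially
    g <- mkGeom()
    a <- array(FALSE, c(9, 80, 3))
    a[3:7, 18:22, ] <- TRUE                  # core, centred near col 20
    a[5, 23:65, 2] <- TRUE                   # medial branch (~9.5 um)
    part <- partitionMedial(mkMask(a, g), boundaryUm = 5)
    ctr <- part$centerIndex
    beyond <- array(FALSE, dim(a))
    beyond[, (ctr + 24):80, ] <- TRUE        # strictly beyond 23 px offset
    expect_identical(maskArray(part$medial), a & beyond)
})

test_that("dye-coupling area averages the window at the dendrite tip", {
    g <- mkGeom()
    dims <- c(40L, 40L, 20L)
    gf <- array(FALSE, dims); gf[18:22, 18:22, 8:15] <- TRUE  # tip slice 8
    ## NB cylinder of radius 2 um spanning the whole stack
    nb <- array(FALSE, dims)
    for (s in 1:20) {
        ctr <- expand.grid(r = 1:40, c = 1:40)
        inside <- ((ctr$r - 20) * 0.22)^2 + ((ctr$c - 20) * 0.22)^2 <= 4
        nb[cbind(ctr$r[inside], ctr$c[inside], s)] <- TRUE
    }
    got <- nbCouplingArea(mkMask(nb, g), mkMask(gf, g), windowLengthUm = 10)
    expect_lt(abs(got - pi * 4) / (pi * 4), 0.1)

    expect_equal(nbCouplingArea(mkMask(array(FALSE, dims), g),
                                mkMask(gf, g)), 0)

    ## NB outside the window is invisible to the measure
    nb2 <- nb
    nb2[, , 17:20] <- TRUE                  # windows 3..12 unaffected
    expect_equal(nbCouplingArea(mkMask(nb2, g), mkMask(gf, g)), got)

    ## tip near the stack edge: window clamps to available slices
    gfEdge <- array(FALSE, dims); gfEdge[18:22, 18:22, 2:6] <- TRUE
    nbHalf <- array(FALSE, dims); nbHalf[1:10, 1:10, 1:4] <- TRUE
    gotEdge <- nbCouplingArea(mkMask(nbHalf, g), mkMask(gfEdge, g))
    ## tip = 2, window clamps to slices 1..10: mean of 4 full + 6 empty
    expect_equal(gotEdge, 100 * 0.22^2 * 4 / 10)

    expect_error(nbCouplingArea(mkMask(nb, g),
                                mkMask(array(FALSE, dims), g)), "empty")
})

test_that("per-region colocalization counts triple conjunctions", {
    set.seed(25)
    g <- mkGeom()
    dims <- c(8L, 8L, 3L)
    shb <- randomMask(dims, g, 0.4)
    regions <- list(JOA = mkMask(array(rep(c(TRUE, FALSE), each = 96),
                                       dims), g),
                    JOB = mkMask(array(rep(c(FALSE, TRUE), each = 96),
                                       dims), g))

    ## identical masks inside a region give 100%
    res <- colocalization(shb, shb, regions["JOA"])
    expect_equal(res$percentColocalized, 100)

    ## disjoint masks give 0%
    inv <- binaryMask(!maskArray(shb), g)
    res0 <- colocalization(shb, inv, regions["JOA"])
    expect_equal(res0$percentColocalized, 0)

    ## random masks match the brute-force triple conjunction
    brp <- randomMask(dims, g, 0.4)
    res2 <- colocalization(shb, brp, regions)
    for (i in 1:2) {
        r <- maskArray(regions[[res2$region[i]]])
        sv <- sum(maskArray(shb) & r) * 0.22^2
        ov <- sum(maskArray(shb) & maskArray(brp) & r) * 0.22^2
        expect_equal(res2$shbVolume[i], sv)
        expect_equal(res2$overlapVolume[i], ov)
        expect_equal(res2$percentColocalized[i], 100 * ov / sv)
    }

    ## an empty region reports 0% with a warning, not an error
    none <- mkMask(array(FALSE, dims), g)
    emptyRegion <- list(JOC = none)
    expect_warning(res3 <- colocalization(none, brp, emptyRegion),
                   "no ShB")
    expect_equal(res3$percentColocalized, 0)
})
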