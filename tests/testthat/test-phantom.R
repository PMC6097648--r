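# Phantom tests use small stacks; the noise- and PSF-free configuration
# below exposes the raw rendered geometry.
cleanSpec <- function(...) {
    phantomSpec(dims = c(64L, 64L, 32L), psfSigmaXY = 0, psfSigmaZ = 0,
                poissonScale = 0, readNoiseSd = 0,
                punctumCount = 20L, azCount = 8L, agglomCount = 2L,
                plaqueCountA = 8L, plaqueCountB = 3L, ...)
}

test_that("a fixed seed reproduces the phantom bit-exactly", {
    s <- phantomSpec(dims = c(48L, 48L, 24L), seed = 9L,
                     punctumCount = 30L, azCount = 6L)
    p1 <- generatePhantom(s)
    p2 <- generatePhantom(s)
    for (ch in channelNames(p1$channels))
        expect_identical(intensities(p1$channels[[ch]]),
                         intensities(p2$channels[[ch]]))
    expect_identical(p1$truth@volumes, p2$truth@volumes)
})

test_that("noise-free truth masks equal the rendered foreground exactly", {
    ph <- generatePhantom(cleanSpec(seed = 14L))
    expect_identical(maskArray(ph$truth@masks$gf),
                     intensities(ph$channels[["GF"]]) > 0L)
    expect_identical(maskArray(ph$truth@masks$plaquesA) |
                     maskArray(ph$truth@masks$plaquesB),
                     intensities(ph$channels[["ShB"]]) > 0L)
})

test_that("voxelized plaque volume approximates the analytic sphere", {
    ## cubic voxels isolate the geometry from slice-step discretization
    ph <- generatePhantom(phantomSpec(
        geometry = mkGeom(dz = 0.22), dims = c(64L, 64L, 64L),
        psfSigmaXY = 0, psfSigmaZ = 0, poissonScale = 0, readNoiseSd = 0,
        punctumCount = 20L, azCount = 8L, agglomCount = 2L,
        plaqueCountA = 10L, plaqueCountB = 1L,
        shbColocFractionA = 0, shbColocFractionB = 0, seed = 31L))
    perPlaque <- ph$truth@volumes[["plaquesA"]] /
        ph$truth@counts[["plaquesA"]]
    analytic <- pi / 6                       # 1 um diameter sphere
    expect_lt(abs(perPlaque - analytic) / analytic, 0.15)
})

test_that("agglomerations contaminate only the Brp-short channel", {
    ph <- generatePhantom(cleanSpec(seed = 15L))
    ag <- maskArray(ph$truth@masks$agglomerations)
    expect_gt(sum(ag), 0)
    expect_true(all(intensities(ph$channels[["Brp"]])[ag] > 0L))
    ## nc82 shows nothing at agglomeration voxels beyond ordinary puncta
    puncta <- maskArray(ph$truth@masks$puncta) |
        maskArray(ph$truth@masks$az)
    expect_true(all(intensities(ph$channels[["nc82"]])[ag & !puncta] == 0L))
})

test_that("oversized objects are rejected with the object named", {
    expect_error(generatePhantom(cleanSpec(branchLengthsUm = 50)),
                 "medial branch")
    expect_error(generatePhantom(cleanSpec(agglomDiameter = 40)),
                 "too small")
})

test_that("PSF blur never shrinks the measured plaque volume", {
    vols <- vapply(c(0.15, 0.3, 0.5), function(sig) {
        ph <- generatePhantom(phantomSpec(
            dims = c(64L, 64L, 32L), seed = 40L, psfSigmaXY = sig,
            psfSigmaZ = 0.4, poissonScale = 0, readNoiseSd = 0,
            plaqueCountA = 8L, plaqueCountB = 3L, punctumCount = 20L,
            azCount = 8L, agglomCount = 2L))
        mask <- binarize(ph$channels[["ShB"]],
                         autoThreshold(ph$channels[["ShB"]], "renyi"))
        maskVolume(mask)
    }, numeric(1))
    expect_true(all(diff(vols) >= 0))
})

test_that("the pipeline recovers plaque volume near truth at defaults", {
    ph <- generatePhantom(phantomSpec(dims = c(96L, 96L, 48L), seed = 18L))
    mask <- binarize(ph$channels[["ShB"]],
                     autoThreshold(ph$channels[["ShB"]], "renyi"))
    truth <- ph$truth@volumes[["plaquesA"]] + ph$truth@volumes[["plaquesB"]]
    expect_lt(abs(maskVolume(mask) - truth) / truth, 0.20)
})

test_that("group studies are reproducible and reject bad multipliers", {
    base <- phantomSpec(dims = c(48L, 48L, 24L), punctumCount = 30L,
                        azCount = 6L, branchLengthsUm = c(2, 3))
    eff <- list(g1 = c(azCount = 1), g2 = c(azCount = 2))
    s1 <- generateGroupStudy(base, eff, nPerGroup = 2L, seed = 5L)
    s2 <- generateGroupStudy(base, eff, nPerGroup = 2L, seed = 5L)
    expect_identical(s1$manifest, s2$manifest)
    expect_identical(
        intensities(s1$specimens[[1]]$channels[["Brp"]]),
        intensities(s2$specimens[[1]]$channels[["Brp"]]))
    expect_error(generateGroupStudy(base, list(g1 = c(azCount = 0)),
                                    nPerGroup = 2L), "multiplier")
    expect_error(generateGroupStudy(base, eff, nPerGroup = 1L), ">= 2")
})

test_that("a four-fold JO-B plaque effect yields a three-to-five-fold measured ratio", {
    base <- testPhantomSpec()
    study <- generateGroupStudy(
        base, list(control = c(jobPlaqueVolume = 1),
                   boosted = c(jobPlaqueVolume = 4)),
        nPerGroup = 8L, seed = 77L)
    out <- runStudy(pipelineConfig(), study)
    m <- aggregate(shbVolume_JOB ~ group, out$results, mean)
    ratio <- m$shbVolume_JOB[m$group == "boosted"] /
        m$shbVolume_JOB[m$group == "control"]
    expect_gte(ratio, 3)
    expect_lte(ratio, 5)
})
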