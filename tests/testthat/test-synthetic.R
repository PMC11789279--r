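test_that("tissue image generator returns ground truth and is seeded", {
    p <- tissueImageParams(clusterPeriodCells = 4, internuclearUm = 10,
                           seed = 1)
    out1 <- genTissueImage(p)
    out2 <- genTissueImage(p)
    expect_equal(out1$truePeriodUm, 40)
    expect_identical(intensityValues(out1$image),
                     intensityValues(out2$image))
    out3 <- genTissueImage(tissueImageParams(seed = 2))
    expect_false(identical(intensityValues(out1$image),
                           intensityValues(out3$image)))
    expect_equal(dim(intensityValues(out1$image)), c(240L, 15L))
})

test_that("with clusters, trend and noise off only the internuclear period remains", {
    p <- tissueImageParams(clusterAmplitude = 0, trendCoeffs = 0,
                           noiseSd = 0)
    out <- genTissueImage(p)
    prof <- detrendProfile(rowMeanProfile(out$image), 2)
    est <- fftDominantPeriod(prof)
    expect_equal(est@periodUm, 10)
})

test_that("tissue parameter validation rejects impossible geometry", {
    expect_error(tissueImageParams(internuclearUm = 0),
                 class = "spinecyto_parameter_error")
    expect_error(tissueImageParams(pixelUm = -1),
                 class = "spinecyto_parameter_error")
    expect_error(tissueImageParams(clusterPeriodCells = 1),
                 class = "spinecyto_parameter_error")
    expect_error(tissueImageParams(noiseSd = -0.1),
                 class = "spinecyto_parameter_error")
})

test_that("log-normal solver matches the quantile function to 0.1%", {
    for (md in c(0.5, 3.4, 6.5)) for (iq in c(0.4, 3.3, 7)) {
        ln <- lognormalFromMedianIqr(md, iq)
        expect_equal(qlnorm(0.5, ln$meanlog, ln$sdlog), md,
                     tolerance = 1e-3)
        expect_equal(diff(qlnorm(c(0.25, 0.75), ln$meanlog, ln$sdlog)),
                     iq, tolerance = 1e-3)
    }
    expect_error(lognormalFromMedianIqr(-1, 2),
                 class = "spinecyto_parameter_error")
    expect_error(lognormalFromMedianIqr(6.5, Inf),
                 class = "spinecyto_parameter_error")
})

test_that("protrusion lengths reproduce the requested median and iqr", {
    l <- genProtrusionLengths(protrusionPopParams(medianUm = 6.5,
                                                  iqrUm = 3.6, n = 10000,
                                                  seed = 42))
    expect_true(all(l > 0))
    expect_gt(median(l), 6.3); expect_lt(median(l), 6.7)
    expect_gt(IQR(l), 3.4); expect_lt(IQR(l), 3.8)
    l2 <- genProtrusionLengths(protrusionPopParams(medianUm = 6.5,
                                                   iqrUm = 3.6, n = 10000,
                                                   seed = 42))
    expect_identical(l, l2)
})

test_that("a vanishing iqr collapses lengths onto the median", {
    l <- genProtrusionLengths(protrusionPopParams(medianUm = 5,
                                                  iqrUm = 1e-6, n = 200,
                                                  seed = 1))
    expect_true(all(abs(l - 5) < 0.01))
})

test_that("track ground truth equals what dynamics recomputes", {
    out <- genTimelapseTracks(protrusionPopParams(n = 50, seed = 7))
    expect_length(out$tracks, 50)
    for (i in seq_len(50)) {
        dyn <- trackDynamics(out$tracks[[i]])
        expect_equal(dyn$maxLengthUm, out$groundTruth$max_length_um[i])
        expect_equal(dyn$lifetimeMin, out$groundTruth$lifetime_min[i])
    }
    # lifetimes are multiples of the 2 min frame interval, minimum 2 min
    expect_true(all(out$groundTruth$lifetime_min %% 2 == 0))
    expect_true(all(out$groundTruth$lifetime_min >= 2))
})

test_that("white-noise generator is calibrated and seeded", {
    expect_identical(profileValues(genWhiteNoiseProfile(50, 1, 0)),
                     rep(0, 50))
    p <- genWhiteNoiseProfile(1e5, 0.5, 1, seed = 3)
    expect_gt(sd(profileValues(p)), 0.99)
    expect_lt(sd(profileValues(p)), 1.01)
    expect_equal(sampleSpacing(p), 0.5)
    expect_identical(profileValues(genWhiteNoiseProfile(64, 1, 1, seed = 5)),
                     profileValues(genWhiteNoiseProfile(64, 1, 1, seed = 5)))
    expect_error(genWhiteNoiseProfile(4, 1, 1),
                 class = "spinecyto_parameter_error")
})

test_that("generators leave the global RNG stream untouched", {
    set.seed(123); before <- .Random.seed
    genTissueImage(tissueImageParams(seed = 9))
    genProtrusionLengths(protrusionPopParams(n = 10, seed = 9))
    genWhiteNoiseProfile(16, 1, 1, seed = 9)
    expect_identical(.Random.seed, before)
})
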