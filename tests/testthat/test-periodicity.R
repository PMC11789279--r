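test_that("ROI extraction respects calibration and bounds", {
    img <- ImageGrid(matrix(rnorm(200 * 30), 200, 30), pixelUm = 1)
    full <- extractRoi(img, RoiBox(0, 200, widthUm = 30))
    expect_identical(intensityValues(full), intensityValues(img))

    roi <- extractRoi(img, RoiBox(0, 200, widthUm = 15, side = "left"))
    expect_equal(ncol(intensityValues(roi)), 15L)
    expect_identical(intensityValues(roi), intensityValues(img)[, 1:15])
    roiR <- extractRoi(img, RoiBox(0, 200, widthUm = 15, side = "right"))
    expect_identical(intensityValues(roiR), intensityValues(img)[, 16:30])

    img05 <- ImageGrid(matrix(0, 200, 40), pixelUm = 0.5)
    sub <- extractRoi(img05, RoiBox(10, 50, widthUm = 10))
    expect_equal(nrow(intensityValues(sub)), 80L)
    expect_equal(pixelSize(sub), 0.5)

    expect_error(extractRoi(img, RoiBox(0, 500)),
                 class = "spinecyto_bounds_error")
    expect_error(extractRoi(img, RoiBox(0, 100, widthUm = 100)),
                 class = "spinecyto_bounds_error")
})

test_that("Gaussian blur preserves constants and matches its transfer function", {
    const <- ImageGrid(matrix(7, 50, 20), 1)
    expect_equal(intensityValues(blurImage(const, 3)),
                 intensityValues(const), tolerance = 1e-12)
    expect_identical(blurImage(const, 0), const)
    expect_error(blurImage(const, -1), class = "spinecyto_parameter_error")

    n <- 400; pos <- 0:(n - 1)
    w <- 51:350    # interior window, away from boundary transients
    for (T in c(10, 20, 40)) {
        x <- sin(2 * pi * pos / T)
        img <- ImageGrid(matrix(rep(x, 5), ncol = 5), 1)
        v <- intensityValues(blurImage(img, 3))[, 3]
        a0 <- sinusoidAmplitude(x[w], pos[w], T)
        a1 <- sinusoidAmplitude(v[w], pos[w], T)
        expect_equal(a1 / a0, exp(-2 * pi^2 * 9 / T^2), tolerance = 0.02)
    }
})

test_that("blur with micrometre calibration converts sigma to pixels", {
    n <- 800; pos <- (0:(n - 1)) * 0.5          # 0.5 um/px
    w <- 101:700
    x <- sin(2 * pi * pos / 10)
    img <- ImageGrid(matrix(rep(x, 4), ncol = 4), 0.5)
    v <- intensityValues(blurImage(img, 3))[, 2]
    expect_equal(sinusoidAmplitude(v[w], pos[w], 10) /
                     sinusoidAmplitude(x[w], pos[w], 10),
                 exp(-2 * pi^2 * 9 / 100), tolerance = 0.02)
})

test_that("row-mean profile averages across the apicobasal axis only", {
    img <- ImageGrid(rbind(c(1, 3), c(2, 2)), 1)
    expect_equal(profileValues(rowMeanProfile(img)), c(2, 2))

    col <- matrix(rnorm(30), ncol = 1)
    expect_equal(profileValues(rowMeanProfile(ImageGrid(col, 2))),
                 as.vector(col))
    expect_equal(sampleSpacing(rowMeanProfile(ImageGrid(col, 2))), 2)

    x <- sin(2 * pi * (0:199) / 40)
    img2 <- ImageGrid(outer(x, rep(1, 10)) + outer(rep(1, 200), rnorm(10)),
                      1)
    prof <- profileValues(rowMeanProfile(img2))
    expect_gt(cor(prof, x), 0.999)
})

test_that("polynomial detrending removes exactly its model class", {
    n <- 200; u <- seq(-1, 1, length.out = n)
    quartic <- 3 + u - 2 * u^2 + 0.5 * u^3 + 4 * u^4
    out <- detrendProfile(Profile1D(quartic, 1), 4)
    expect_lt(max(abs(profileValues(out))), 1e-8 * max(abs(quartic)))

    s <- sin(2 * pi * (0:(n - 1)) / 20)
    out2 <- detrendProfile(Profile1D(quartic + s, 1), 4)
    expect_gt(cor(profileValues(out2), s), 0.99)
    expect_lt(abs(mean(profileValues(out2))), 1e-10)

    out3 <- detrendProfile(Profile1D(rep(5, 50), 1), 4)
    expect_equal(profileValues(out3), rep(0, 50), tolerance = 1e-10)

    expect_error(detrendProfile(Profile1D(rnorm(8), 1), 8),
                 class = "spinecyto_length_error")
})
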