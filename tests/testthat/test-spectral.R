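test_that("periodogram matches the direct DFT oracle and Parseval", {
    set.seed(1)
    for (n in c(16, 17, 32, 63, 64)) {
        x <- rnorm(n)
        pg <- periodogram(Profile1D(x, 1))
        expect_equal(pg@power, naiveDftPower(x), tolerance = 1e-9)
        # one-sided Parseval with half-weighted Nyquist: interior
        # ordinates count twice, the Nyquist once
        xc <- x - mean(x)
        expect_equal(2 * sum(pg@weights * pg@power), sum(xc^2),
                     tolerance = 1e-6)
    }
})

test_that("a pure integer-cycle sinusoid concentrates all power in one bin", {
    n <- 120
    x <- sin(2 * pi * 5 * (0:(n - 1)) / n)
    pg <- periodogram(Profile1D(x, 1))
    expect_equal(which.max(pg@power), 5L)
    expect_gt(pg@power[5] / sum(pg@power), 1 - 1e-9)
    expect_equal(pg@periodsUm[5], n / 5)
})

test_that("Fisher g-test is exact in its closed-form corners", {
    n <- 121
    x <- sin(2 * pi * 11 * (0:(n - 1)) / n)
    expect_equal(fisherGTest(periodogram(Profile1D(x, 1))), 0)
    expect_error(fisherGTest(periodogram(Profile1D(rep(0, 32), 1))),
                 class = "spinecyto_degenerate_error")
})

test_that("Fisher g-test p matches a Monte-Carlo exponential-spectrum oracle", {
    # m = 8 exponential ordinates: compare the closed-form tail with the
    # empirical null of g = max/sum
    m <- 8
    pg <- new("PeriodogramResult", periodsUm = 64 / (1:m),
              power = c(5, 1.2, 0.3, 0.8, 1.1, 0.6, 0.2, 0.9),
              weights = rep(1, m), nSamples = 64L, spacingUm = 1)
    p <- fisherGTest(pg)
    gObs <- 5 / sum(pg@power)
    set.seed(11)
    E <- matrix(rexp(m * 2e5), nrow = m)
    gNull <- apply(E, 2, max) / colSums(E)
    expect_lt(abs(p - mean(gNull >= gObs)), 0.01)
})

test_that("dominant period reads the right bin and flags significance", {
    pos <- 0:239
    est <- fftDominantPeriod(Profile1D(sin(2 * pi * pos / 40), 1))
    expect_equal(est@periodUm, 40)
    expect_true(est@significant)

    two <- 2 * sin(2 * pi * pos / 40) + sin(2 * pi * pos / 24)
    expect_equal(fftDominantPeriod(Profile1D(two, 1))@periodUm, 40)

    # exact power tie: lowest frequency (largest period) wins
    pgTie <- new("PeriodogramResult", periodsUm = 240 / (1:6),
                 power = c(1, 5, 2, 5, 0.5, 1), weights = rep(1, 6),
                 nSamples = 240L, spacingUm = 1)
    expect_identical(spinecyto:::selectDominant(pgTie), 2L)

    # the k = 1 ordinate (period = span) is never reported
    n <- 240
    slow <- cos(2 * pi * pos / n)
    expect_lte(fftDominantPeriod(Profile1D(slow, 1))@periodUm, n / 2)
})

test_that("non-significant estimates still carry their period", {
    prof <- genWhiteNoiseProfile(101, 1, 1, seed = 202)
    est <- fftDominantPeriod(prof)
    expect_false(is.na(est@periodUm))
    expect_identical(est@significant, est@pValue <= 0.05)
})

test_that("group comparison reproduces the exact rank-test corners", {
    expect_equal(compareGroups(c(1, 2), c(3, 4))$pValue, 1 / 3,
                 tolerance = 1e-12)
    expect_equal(compareGroups(c(1, 2, 5), c(1, 2, 5))$pValue, 1)
    expect_error(compareGroups(numeric(0), 1:3),
                 class = "spinecyto_parameter_error")
})

test_that("exact rank test agrees with a permutation oracle", {
    set.seed(21)
    for (rep in 1:3) {
        a <- rnorm(5); b <- rnorm(5, mean = 0.8)
        p <- compareGroups(a, b)$pValue
        expect_lt(abs(p - permutationUTest(a, b, nPerm = 40000,
                                           seed = rep)), 0.01)
    }
})
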