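test_that("trace length sums segments and is rigid-motion invariant", {
    expect_equal(traceLength(FilamentTrace(rbind(c(0, 0, 0), c(3, 4, 0)))),
                 5)
    expect_equal(traceLength(FilamentTrace(rbind(c(0, 0, 0), c(1, 0, 0),
                                                 c(2, 0, 0)))), 2)
    set.seed(51)
    pts <- matrix(rnorm(30), ncol = 3)
    tr <- FilamentTrace(pts)
    oracle <- sum(sqrt(rowSums((pts[-1, ] - pts[-10, ])^2)))
    expect_equal(traceLength(tr), oracle, tolerance = 1e-12)
    # rigid rotation about z plus translation
    th <- 0.83
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    moved <- FilamentTrace(pts %*% t(R) +
                               matrix(c(5, -2, 1), 10, 3, byrow = TRUE))
    expect_equal(traceLength(moved), traceLength(tr), tolerance = 1e-10)
    expect_error(FilamentTrace(matrix(c(0, 0, 0), 1, 3)))
})

test_that("protrusion angles follow the apical/basal sign convention", {
    frL <- axisFrame("left")      # apical = +x
    frR <- axisFrame("right")     # apical = -x
    dvOnly <- FilamentTrace(rbind(c(0, 0, 0), c(0, 5, 0)))
    expect_equal(protrusionAngle(dvOnly, frL), 0)

    apicalL <- FilamentTrace(rbind(c(0, 0, 0), c(5, 0, 0)), side = "left")
    expect_equal(protrusionAngle(apicalL, frL), -90)
    apicalR <- FilamentTrace(rbind(c(0, 0, 0), c(-5, 0, 0)),
                             side = "right")
    expect_equal(protrusionAngle(apicalR, frR), -90)

    basal45 <- FilamentTrace(rbind(c(0, 0, 0), c(-3, 3, 0)), side = "left")
    expect_equal(protrusionAngle(basal45, frL), 45)

    # left/right mirror of the same trace gives the same angle
    set.seed(8)
    for (i in 1:10) {
        chord <- rnorm(3)
        tl <- FilamentTrace(rbind(c(0, 0, 0), chord), side = "left")
        tr <- FilamentTrace(rbind(c(0, 0, 0), chord * c(-1, 1, 1)),
                            side = "right")
        expect_equal(protrusionAngle(tl, frL), protrusionAngle(tr, frR))
    }
    degen <- FilamentTrace(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
    expect_error(protrusionAngle(degen, frL),
                 class = "spinecyto_degenerate_error")
})

test_that("density is protrusions per micrometre of traced cell", {
    expect_equal(protrusionDensity(10, 50), 0.2)
    expect_equal(protrusionDensity(0, 50), 0)
    expect_equal(protrusionDensity(10, 25), 2 * protrusionDensity(10, 50))
    expect_error(protrusionDensity(3, 0),
                 class = "spinecyto_parameter_error")
})

test_that("track dynamics recover max extension, lifetime and angle", {
    mk <- function(len, t) FilamentTrace(rbind(c(0, 0, 0), c(0, len, 0)),
                                         frameTimeMin = t)
    tr <- ProtrusionTrack(list(mk(2, 0), mk(6.5, 2), mk(3, 4)),
                          frameIntervalMin = 2)
    dyn <- trackDynamics(tr, axisFrame("left"))
    expect_equal(dyn$maxLengthUm, 6.5)
    expect_equal(dyn$lifetimeMin, 6)
    expect_equal(dyn$angleAtMaxDeg, 0)

    single <- ProtrusionTrack(list(mk(4, 0)), frameIntervalMin = 2)
    expect_equal(trackDynamics(single)$lifetimeMin, 2)
})

test_that("median/iqr summary uses interpolated quantiles", {
    s <- summariseMedianIqr(1:5)
    expect_equal(s$median, 3); expect_equal(s$iqr, 2); expect_equal(s$n, 5)
    expect_equal(summariseMedianIqr(rep(7, 10))$iqr, 0)
    ln <- lognormalFromMedianIqr(6.5, 3.6)
    set.seed(61)
    big <- rlnorm(2e5, ln$meanlog, ln$sdlog)
    s2 <- summariseMedianIqr(big)
    expect_equal(s2$median, 6.5, tolerance = 0.01)
    expect_equal(s2$iqr, 3.6, tolerance = 0.01)
    expect_error(summariseMedianIqr(numeric(0)),
                 class = "spinecyto_parameter_error")
})

test_that("lifetime outlier exclusion logs and is idempotent", {
    mk <- function(nFrames) {
        traces <- lapply(seq_len(nFrames), function(f)
            FilamentTrace(rbind(c(0, 0, 0), c(0, 1, 0)),
                          frameTimeMin = (f - 1) * 2))
        ProtrusionTrack(traces, frameIntervalMin = 2)
    }
    tracks <- list(mk(2), mk(3), mk(75))       # lifetimes 4, 6, 150 min
    out <- excludeOutliers(tracks, lifetimeCapMin = 100)
    expect_length(out$tracks, 2)
    expect_equal(out$exclusions$lifetime_min, 150)
    expect_match(out$exclusions$reason, "exceeds cap")
    again <- excludeOutliers(out$tracks, 100)
    expect_length(again$tracks, 2)
    expect_equal(nrow(again$exclusions), 0)
    all3 <- excludeOutliers(tracks, Inf)
    expect_length(all3$tracks, 3)
})

test_that("puncta counting thresholds on background and merges close peaks", {
    pos <- seq(0, 20, by = 0.1)
    bg <- rep(1, 100) + rep(c(-0.05, 0.05), 50)
    expect_equal(countDll1Puncta(rep(1, length(pos)), pos, bg), 0)

    one <- 1 + 10 * exp(-(pos - 10)^2 / (2 * 0.3^2))
    expect_equal(countDll1Puncta(one, pos, bg), 1)

    two <- 1 + 10 * exp(-(pos - 8)^2 / (2 * 0.3^2)) +
        9 * exp(-(pos - 14)^2 / (2 * 0.3^2))
    expect_equal(countDll1Puncta(two, pos, bg), 2)

    # bumps 0.5 um apart merge under the default 1 um separation, and an
    # exhaustive maxima enumeration confirms two raw peaks existed
    close2 <- 1 + 10 * exp(-(pos - 10)^2 / (2 * 0.12^2)) +
        9 * exp(-(pos - 10.5)^2 / (2 * 0.12^2))
    i <- 2:(length(close2) - 1)
    rawPeaks <- sum(close2[i] > close2[i - 1] & close2[i] > close2[i + 1] &
                    close2[i] > median(bg) + 3 * mad(bg))
    expect_equal(rawPeaks, 2)
    expect_equal(countDll1Puncta(close2, pos, bg), 1)
    expect_equal(countDll1Puncta(close2, pos, bg, minSepUm = 0.3), 2)
})

test_that("length classes use right-open edges at exactly 5 and 10 um", {
    out <- angleLengthBins(c(0, 10, -30), c(4.9, 5.0, 10.0))
    sums <- tapply(out$count, out$length_class, sum)
    expect_equal(as.vector(sums[c("<5", "5-10", ">10")]), c(1, 1, 1))
    expect_equal(sum(out$count), 3)
    # empty class allowed
    out2 <- angleLengthBins(c(0, 5), c(1, 2))
    expect_equal(sum(out2$count[out2$length_class != "<5"]), 0)
    expect_equal(sum(out2$count), 2)
})
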