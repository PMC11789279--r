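#' Parameters for the synthetic tissue-image generator
#'
#' Describes the statistical structure the spatial-period pipeline
#' assumes of a neuroepithelial fluorescence image: nuclei spaced about
#' 10 um apart along the dorsoventral (DV) axis, microclusters of high
#' and low expression alternating with a spatial period of 3-5 cell
#' diameters, a smooth domain-edge intensity trend, and additive noise.
#'
#' The defaults encode the study conditions: 10 um internuclear spacing,
#' a 4-cell cluster period (hence a 40 um ground-truth spatial period),
#' 50% high/low cluster contrast, a gentle quadratic domain trend that
#' vanishes at the DV edges, and noise at 10% of the nuclear bump
#' amplitude.
#'
#' @param nCellsDv number of nuclei along the DV axis (default 24, i.e.
#'   a 240 um domain at the default spacing).
#' @param internuclearUm distance between neighbouring nuclei in um
#'   (default 10).
#' @param clusterPeriodCells cluster period in cell diameters (default 4;
#'   the biological range is 3-5).
#' @param clusterAmplitude relative intensity contrast of high versus low
#'   microclusters (default 0.5; 0 disables clustering).
#' @param trendCoeffs polynomial coefficients (intercept first) of the
#'   smooth DV trend, evaluated on normalised position u in [0, 1].
#'   Default `c(0, 1, -1)`: an order-2 bump peaking mid-domain and
#'   vanishing at the edges, emulating domain-boundary falloff.
#' @param noiseSd standard deviation of additive Gaussian noise, in units
#'   of the (unit) nuclear bump amplitude (default 0.1).
#' @param pixelUm micrometres per pixel (default 1).
#' @param roiHeightUm apicobasal extent of the image in um (default 15).
#' @param seed RNG seed for the noise (default 1).
#' @return A validated parameter list of class `TissueImageParams`.
#' @seealso [genTissueImage()]
#' @export
tissueImageParams <- function(nCellsDv = 24, internuclearUm = 10,
                              clusterPeriodCells = 4,
                              clusterAmplitude = 0.5,
                              trendCoeffs = c(0, 1, -1),
                              noiseSd = 0.1, pixelUm = 1,
                              roiHeightUm = 15, seed = 1) {
    stopIfNot(internuclearUm > 0, "'internuclearUm' must be positive")
    stopIfNot(clusterPeriodCells >= 2, "'clusterPeriodCells' must be >= 2")
    stopIfNot(pixelUm > 0, "'pixelUm' must be positive")
    stopIfNot(noiseSd >= 0, "'noiseSd' must be non-negative")
    stopIfNot(nCellsDv >= 2, "'nCellsDv' must be at least 2")
    stopIfNot(roiHeightUm > 0, "'roiHeightUm' must be positive")
    structure(list(nCellsDv = nCellsDv, internuclearUm = internuclearUm,
                   clusterPeriodCells = clusterPeriodCells,
                   clusterAmplitude = clusterAmplitude,
                   trendCoeffs = trendCoeffs, noiseSd = noiseSd,
                   pixelUm = pixelUm, roiHeightUm = roiHeightUm,
                   seed = seed),
              class = "TissueImageParams")
}

#' Parameters for synthetic protrusion populations
#'
#' Length and lifetime populations are parameterised by their median and
#' interquartile range, the summary statistics used throughout the
#' morphometry. Defaults reproduce the live-imaging population: maximum
#' extension length 6.5 +/- 3.6 um and lifetime 4 +/- 7 min
#' (median +/- i.q.r.), sampled at a 2 min frame interval.
#'
#' @param medianUm population median maximum length in um (default 6.5).
#' @param iqrUm population interquartile range of length in um
#'   (default 3.6).
#' @param n number of protrusions/tracks to generate.
#' @param lifetimeMedianMin median lifetime in minutes (default 4).
#' @param lifetimeIqrMin interquartile range of lifetime in minutes
#'   (default 7).
#' @param frameIntervalMin imaging frame interval in minutes (default 2).
#' @param seed RNG seed.
#' @return A validated parameter list of class `ProtrusionPopParams`.
#' @seealso [genProtrusionLengths()], [genTimelapseTracks()]
#' @export
protrusionPopParams <- function(medianUm = 6.5, iqrUm = 3.6, n = 100,
                                lifetimeMedianMin = 4, lifetimeIqrMin = 7,
                                frameIntervalMin = 2, seed = 1) {
    stopIfNot(medianUm > 0, "'medianUm' must be positive")
    stopIfNot(iqrUm > 0, "'iqrUm' must be positive")
    stopIfNot(n >= 1, "'n' must be at least 1")
    stopIfNot(frameIntervalMin > 0, "'frameIntervalMin' must be positive")
    stopIfNot(lifetimeMedianMin > 0, "'lifetimeMedianMin' must be positive")
    stopIfNot(lifetimeIqrMin > 0, "'lifetimeIqrMin' must be positive")
    structure(list(medianUm = medianUm, iqrUm = iqrUm, n = n,
                   lifetimeMedianMin = lifetimeMedianMin,
                   lifetimeIqrMin = lifetimeIqrMin,
                   frameIntervalMin = frameIntervalMin, seed = seed),
              class = "ProtrusionPopParams")
}

#' Solve log-normal parameters from a median and interquartile range
#'
#' The quantile function of the log-normal gives
#' `median = exp(mu)` and `iqr = 2 * median * sinh(z75 * sigma)` with
#' `z75 = qnorm(0.75)`, so both parameters invert in closed form. Used by
#' the protrusion generators; exported because the same parameterisation
#' backs the distributional checks.
#'
#' @param medianVal population median (> 0).
#' @param iqrVal population interquartile range (> 0).
#' @return list with components `meanlog` and `sdlog`.
#' @examples
#' p <- lognormalFromMedianIqr(6.5, 3.6)
#' qlnorm(0.5, p$meanlog, p$sdlog)                       # 6.5
#' diff(qlnorm(c(0.25, 0.75), p$meanlog, p$sdlog))       # 3.6
#' @export
lognormalFromMedianIqr <- function(medianVal, iqrVal) {
    stopIfNot(is.finite(medianVal) && medianVal > 0,
              "median must be positive and finite")
    stopIfNot(is.finite(iqrVal) && iqrVal > 0,
              "iqr must be positive and finite")
    meanlog <- log(medianVal)
    sdlog <- asinh(iqrVal / (2 * medianVal)) / stats::qnorm(0.75)
    list(meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic periodically patterned tissue image
#'
#' Renders nuclei as isotropic Gaussian bumps (sd 2.5 um) on a lattice
#' with the given internuclear spacing, modulates the nuclear intensities
#' along the dorsoventral axis with a raised-cosine microcluster envelope
#' of period `clusterPeriodCells * internuclearUm`, adds a smooth
#' polynomial trend and Gaussian noise. The raised cosine is used because
#' it is smooth and introduces no strong harmonics that would bias the
#' periodogram readout.
#'
#' @param params a [tissueImageParams()] list.
#' @return list with components `image` (an [ImageGrid-class]) and
#'   `truePeriodUm` (the ground-truth cluster period,
#'   `clusterPeriodCells * internuclearUm`).
#' @examples
#' out <- genTissueImage(tissueImageParams(seed = 7))
#' out$truePeriodUm          # 40
#' out$image
#' @export
genTissueImage <- function(params = tissueImageParams()) {
    stopifnot(inherits(params, "TissueImageParams"))
    p <- params
    lenUm <- p$nCellsDv * p$internuclearUm
    nRow <- max(8L, round(lenUm / p$pixelUm))
    nCol <- max(1L, round(p$roiHeightUm / p$pixelUm))
    x <- (seq_len(nRow) - 0.5) * p$pixelUm    # DV position, um
    y <- (seq_len(nCol) - 0.5) * p$pixelUm    # AB position, um

    nucSd <- 2.5   # um; nucleus-like bump width, only the spacing matters
    dvCentres <- (seq_len(p$nCellsDv) - 0.5) * p$internuclearUm
    abCentres <- (seq_len(max(1L, ceiling(p$roiHeightUm /
                                          p$internuclearUm))) - 0.5) *
        p$internuclearUm
    gx <- rowSums(exp(-outer(x, dvCentres, "-")^2 / (2 * nucSd^2)))
    gy <- rowSums(exp(-outer(y, abCentres, "-")^2 / (2 * nucSd^2)))

    periodUm <- p$clusterPeriodCells * p$internuclearUm
    envelope <- 1 + (p$clusterAmplitude / 2) * cos(2 * pi * x / periodUm)
    u <- x / lenUm
    trend <- rep(0, nRow)
    if (length(p$trendCoeffs))
        for (j in seq_along(p$trendCoeffs))
            trend <- trend + p$trendCoeffs[j] * u^(j - 1)

    img <- outer(gx * envelope, gy) + trend
    if (p$noiseSd > 0)
        img <- img + withLocalSeed(p$seed,
            matrix(stats::rnorm(nRow * nCol, sd = p$noiseSd), nRow, nCol))
    list(image = ImageGrid(img, p$pixelUm), truePeriodUm = periodUm)
}

#' Generate protrusion lengths from a median/iqr-matched log-normal
#'
#' Lengths are drawn from the log-normal distribution whose median and
#' interquartile range equal the requested population values (solved via
#' the quantile function, see [lognormalFromMedianIqr()]); the log-normal
#' reproduces the strongly right-skewed length distributions seen in
#' tissue. All samples are strictly positive.
#'
#' @param params a [protrusionPopParams()] list.
#' @return numeric vector of `params$n` lengths in um.
#' @examples
#' l <- genProtrusionLengths(protrusionPopParams(n = 1000, seed = 2))
#' stats::median(l)   # close to 6.5
#' @export
genProtrusionLengths <- function(params = protrusionPopParams()) {
    stopifnot(inherits(params, "ProtrusionPopParams"))
    ln <- lognormalFromMedianIqr(params$medianUm, params$iqrUm)
    withLocalSeed(params$seed,
        stats::rlnorm(params$n, ln$meanlog, ln$sdlog))
}

#' Generate time-lapse protrusion tracks with ground truth
#'
#' Each track draws a maximum extension length and a lifetime from the
#' median/iqr-matched log-normals, quantises the lifetime to the frame
#' interval (minimum one frame), and renders straight filament snapshots
#' whose length follows a triangular extend-then-retract profile peaking
#' at the drawn maximum. The ground truth for every track is returned so
#' dynamics recovery can be checked exactly.
#'
#' @param params a [protrusionPopParams()] list.
#' @return list with components `tracks` (list of
#'   [ProtrusionTrack-class]) and `groundTruth` (data.frame with columns
#'   `track_id`, `max_length_um`, `lifetime_min`).
#' @examples
#' out <- genTimelapseTracks(protrusionPopParams(n = 5, seed = 3))
#' out$groundTruth
#' @export
genTimelapseTracks <- function(params = protrusionPopParams()) {
    stopifnot(inherits(params, "ProtrusionPopParams"))
    lenPar <- lognormalFromMedianIqr(params$medianUm, params$iqrUm)
    lifPar <- lognormalFromMedianIqr(params$lifetimeMedianMin,
                                     params$lifetimeIqrMin)
    dt <- params$frameIntervalMin
    withLocalSeed(params$seed, {
        maxLen <- stats::rlnorm(params$n, lenPar$meanlog, lenPar$sdlog)
        lifRaw <- stats::rlnorm(params$n, lifPar$meanlog, lifPar$sdlog)
        nFrames <- pmax(1L, as.integer(round(lifRaw / dt)))
        theta <- stats::runif(params$n, 0, 2 * pi)
        tracks <- vector("list", params$n)
        for (i in seq_len(params$n)) {
            nf <- nFrames[i]
            pk <- ceiling(nf / 2)
            frac <- ifelse(seq_len(nf) <= pk,
                           seq_len(nf) / pk,
                           (nf + 1 - seq_len(nf)) / (nf + 1 - pk))
            lens <- maxLen[i] * pmax(frac, 1e-3)
            dir3 <- c(cos(theta[i]), sin(theta[i]), 0)
            traces <- lapply(seq_len(nf), function(f)
                FilamentTrace(rbind(c(0, 0, 0), dir3 * lens[f]),
                              cellId = sprintf("cell%04d", i),
                              frameTimeMin = (f - 1) * dt))
            tracks[[i]] <- ProtrusionTrack(traces, frameIntervalMin = dt)
        }
        list(tracks = tracks,
             groundTruth = data.frame(
                 track_id = sprintf("track%04d", seq_len(params$n)),
                 max_length_um = maxLen,
                 lifetime_min = nFrames * dt))
    })
}

#' Generate a white-noise intensity profile
#'
#' I.i.d. Gaussian samples with mean zero, used as the null input for
#' calibrating the Fisher g-test and the bootstrap ACF threshold.
#'
#' @param nSamples number of samples (>= 8).
#' @param spacingUm sample spacing in um.
#' @param sd noise standard deviation.
#' @param seed RNG seed.
#' @return A [Profile1D-class].
#' @examples
#' genWhiteNoiseProfile(64, 1, 1, seed = 1)
#' @export
genWhiteNoiseProfile <- function(nSamples, spacingUm = 1, sd = 1,
                                 seed = NULL) {
    stopIfNot(nSamples >= 8, "'nSamples' must be at least 8")
    stopIfNot(sd >= 0, "'sd' must be non-negative")
    vals <- if (sd == 0) rep(0, nSamples)
            else withLocalSeed(seed, stats::rnorm(nSamples, sd = sd))
    Profile1D(vals, spacingUm)
}
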