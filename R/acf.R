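#' Normalised autocorrelation of a detrended profile
#'
#' Biased autocovariance (divide by n) normalised by its lag-0 value, so
#' `r(0) = 1` and `|r| <= 1`. Lags are restricted to at most half the
#' profile length: beyond that too few sample pairs remain and the
#' estimate is dominated by edge noise. Computed via FFT (circular
#' convolution on a zero-padded signal, equivalent to the direct sum).
#'
#' @param profile a detrended [Profile1D-class] with non-zero variance.
#' @return An [AcfResult-class] with lags `0..floor(n/2)` samples.
#' @examples
#' prof <- Profile1D(cos(2 * pi * (0:239) / 40), 1)
#' autocorrelation(prof)
#' @export
autocorrelation <- function(profile) {
    stopifnot(is(profile, "Profile1D"))
    stopIfNot(length(profile@values) >= 8L,
              "need at least 8 samples for the ACF")
    x <- profile@values - mean(profile@values)
    if (sum(x^2) == 0)
        stop(errorCondition("zero-variance profile: ACF undefined",
                            class = c("spinecyto_degenerate_error",
                                      "error", "condition")))
    r <- acfFft(x)
    L <- length(x) %/% 2L
    new("AcfResult", lagsUm = (0:L) * profile@spacingUm,
        r = r[seq_len(L + 1L)], threshold = numeric(0))
}

# Full-length biased normalised ACF of a centred vector, via FFT.
acfFft <- function(x) {
    n <- length(x)
    np <- stats::nextn(2L * n, 2)
    X <- stats::fft(c(x, rep(0, np - n)))
    s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / np
    r <- s[seq_len(n)] / s[1L]
    pmin(pmax(r, -1), 1)
}

#' Permutation-bootstrap significance threshold for ACF peaks
#'
#' Builds the per-lag null envelope for ACF peaks by repeatedly shuffling
#' the detrended profile values (permutation without replacement, which
#' destroys all serial structure while keeping the marginal intensity
#' distribution), recomputing the ACF of each shuffle, and taking the
#' one-sided upper `(1 - alpha)` quantile at each lag. The threshold is
#' per-lag, not family-wise, matching the grey-envelope depiction of the
#' pipeline. Deterministic given `seed`.
#'
#' @param profile the detrended [Profile1D-class] the ACF was computed
#'   from.
#' @param nBoot number of permutation resamples (default 1000; fewer than
#'   100 triggers a warning).
#' @param alpha one-sided significance level (default 0.05).
#' @param seed RNG seed.
#' @return numeric vector of per-lag thresholds aligned with the lags of
#'   [autocorrelation()] (the lag-0 entry is 1 by construction).
#' @examples
#' prof <- genWhiteNoiseProfile(128, 1, 1, seed = 1)
#' thr <- bootstrapAcfThreshold(prof, nBoot = 200, seed = 2)
#' @export
bootstrapAcfThreshold <- function(profile, nBoot = 1000, alpha = 0.05,
                                  seed = NULL) {
    stopifnot(is(profile, "Profile1D"))
    if (nBoot < 100)
        warning("nBoot < 100 gives an unstable threshold quantile")
    x <- profile@values - mean(profile@values)
    if (sum(x^2) == 0)
        stop(errorCondition("zero-variance profile: ACF undefined",
                            class = c("spinecyto_degenerate_error",
                                      "error", "condition")))
    n <- length(x)
    L <- n %/% 2L
    np <- stats::nextn(2L * n, 2)
    perm <- withLocalSeed(seed,
        vapply(seq_len(nBoot), function(i) sample(x, n), numeric(n)))
    padded <- rbind(perm, matrix(0, np - n, nBoot))
    P <- Mod(stats::mvfft(padded))^2
    S <- Re(stats::mvfft(P, inverse = TRUE)) / np
    R <- sweep(S[seq_len(L + 1L), , drop = FALSE], 2, S[1L, ], "/")
    apply(R, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)
}

#' Attach a significance threshold to an ACF result
#'
#' @param acf an [AcfResult-class].
#' @param threshold per-lag threshold vector matching the ACF lags, e.g.
#'   from [bootstrapAcfThreshold()].
#' @return The [AcfResult-class] with threshold attached.
#' @export
setAcfThreshold <- function(acf, threshold) {
    stopifnot(is(acf, "AcfResult"))
    stopIfNot(length(threshold) == length(acf@r),
              "threshold length must match the number of ACF lags")
    initialize(acf, threshold = as.numeric(threshold))
}

#' Spatial period from significant ACF peak spacings
#'
#' Identifies significant ACF peaks -- strict local maxima over a
#' 3-sample neighbourhood at positive lag whose value exceeds the
#' per-lag bootstrap threshold -- and averages the spacings between
#' consecutive significant peaks. The first spacing counted runs from
#' lag 0 to the first significant peak, then successive peak-to-peak
#' gaps, so equally spaced peaks at lags P, 2P, 3P give period P. When
#' no peak clears the threshold no period is returned (`periodUm = NA`).
#'
#' @param acf an [AcfResult-class] with threshold attached (see
#'   [setAcfThreshold()]).
#' @return A [PeriodEstimate-class] with `method = "ACF"`.
#' @examples
#' prof <- detrendProfile(rowMeanProfile(blurImage(
#'     genTissueImage(tissueImageParams(seed = 4))$image)))
#' a <- autocorrelation(prof)
#' a <- setAcfThreshold(a, bootstrapAcfThreshold(prof, 200, seed = 5))
#' acfPeriod(a)
#' @export
acfPeriod <- function(acf) {
    stopifnot(is(acf, "AcfResult"))
    stopIfNot(length(acf@threshold) > 0,
              "ACF has no significance threshold attached")
    r <- acf@r
    n <- length(r)
    isPeak <- rep(FALSE, n)
    if (n >= 3L) {
        i <- 2:(n - 1L)
        isPeak[i] <- r[i] > r[i - 1L] & r[i] > r[i + 1L]
    }
    sig <- which(isPeak & r > acf@threshold & acf@lagsUm > 0)
    if (!length(sig))
        return(new("PeriodEstimate", method = "ACF", periodUm = NA_real_,
                   pValue = NA_real_, significant = FALSE,
                   sigPeakLagsUm = numeric(0)))
    peakLags <- acf@lagsUm[sig]
    spacings <- diff(c(0, peakLags))
    new("PeriodEstimate", method = "ACF", periodUm = mean(spacings),
        pValue = NA_real_, significant = TRUE, sigPeakLagsUm = peakLags)
}
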