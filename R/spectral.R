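#' Discrete periodogram of a detrended profile
#'
#' Computes the discrete Fourier power `I_k = |X_k|^2 / n` at the
#' positive frequencies k = 1..floor(n/2), excluding the zero-frequency
#' ordinate. No zero-padding is applied, so the reported periods are
#' exactly `n * spacing / k`. For even n the Nyquist ordinate is kept but
#' carries weight 1/2 in the Fisher g-test sum (it has one degree of
#' freedom where interior ordinates have two).
#'
#' @param profile a detrended [Profile1D-class].
#' @return A [PeriodogramResult-class].
#' @examples
#' p <- Profile1D(sin(2 * pi * (0:239) / 40), 1)
#' pg <- periodogram(p)
#' pg
#' @export
periodogram <- function(profile) {
    stopifnot(is(profile, "Profile1D"))
    x <- profile@values
    n <- length(x)
    stopIfNot(n >= 8L, "need at least 8 samples for spectral analysis")
    X <- stats::fft(x)
    m <- n %/% 2L
    k <- seq_len(m)
    pw <- Mod(X[k + 1L])^2 / n
    w <- rep(1, m)
    if (n %% 2L == 0L) w[m] <- 0.5
    new("PeriodogramResult", periodsUm = n * profile@spacingUm / k,
        power = pw, weights = w, nSamples = as.integer(n),
        spacingUm = profile@spacingUm)
}

#' Fisher g-test for the largest periodogram ordinate
#'
#' Tests the dominant spectral peak against the null of i.i.d. Gaussian
#' noise. The statistic is `g = max_k w_k I_k / sum_k w_k I_k` and the
#' exact null tail probability is the classical alternating series
#' `p = sum_{j=1}^{floor(1/g)} (-1)^(j-1) C(m, j) (1 - j g)^(m-1)`,
#' clamped to `[0, 1]`, with m the number of ordinates. Terms are
#' accumulated on the log scale for numerical stability at large m.
#'
#' @param pg a [PeriodogramResult-class] with at least 2 ordinates.
#' @return the p-value.
#' @examples
#' p <- Profile1D(sin(2 * pi * (0:239) / 40), 1)
#' fisherGTest(periodogram(p))   # ~0: all power in one ordinate
#' @export
fisherGTest <- function(pg) {
    stopifnot(is(pg, "PeriodogramResult"))
    m <- length(pg@power)
    stopIfNot(m >= 2L, "need at least 2 periodogram ordinates")
    wI <- pg@weights * pg@power
    tot <- sum(wI)
    if (tot <= 0)
        stop(errorCondition("all-zero spectrum: g statistic undefined",
                            class = c("spinecyto_degenerate_error",
                                      "error", "condition")))
    g <- max(wI) / tot
    jMax <- min(m, floor(1 / g))
    j <- seq_len(jMax)
    logTerms <- lchoose(m, j) + (m - 1) * log1p(-j * g)
    p <- sum((-1)^(j - 1) * exp(logTerms))
    min(max(p, 0), 1)
}

#' Dominant spatial period with Fisher g-test significance
#'
#' Reads the spatial period off a detrended profile as the period of the
#' maximum-power periodogram ordinate. Periods longer than half the
#' profile span (the k = 1 ordinate) are suppressed from reporting to
#' guard against residual trend leakage; ties in power resolve to the
#' largest period. The Fisher g-test p-value for the spectrum is
#' attached, and the estimate is flagged non-significant when
#' `p > alpha` (the period is still reported, with the flag carried).
#'
#' @param profile a detrended [Profile1D-class].
#' @param alpha significance level for the g-test flag (default 0.05).
#' @return A [PeriodEstimate-class] with `method = "FFT"`.
#' @examples
#' prof <- Profile1D(sin(2 * pi * (0:239) / 40), 1)
#' fftDominantPeriod(prof)   # 40 um
#' @export
fftDominantPeriod <- function(profile, alpha = 0.05) {
    stopifnot(is(profile, "Profile1D"))
    pg <- periodogram(profile)
    p <- fisherGTest(pg)
    k <- selectDominant(pg)
    new("PeriodEstimate", method = "FFT", periodUm = pg@periodsUm[k],
        pValue = p, significant = p <= alpha, sigPeakLagsUm = numeric(0))
}

# Index of the reported dominant ordinate: the k = 1 ordinate (period =
# full span) is suppressed as trend leakage, and power ties resolve to
# the lowest frequency (largest period), deterministically.
selectDominant <- function(pg) {
    pwr <- pg@power
    pwr[1L] <- -Inf                       # period <= span / 2 only
    which.max(pwr)                        # first max = largest period
}

#' Two-group comparison of spatial periods (Mann-Whitney U)
#'
#' Two-tailed Mann-Whitney/Wilcoxon rank-sum comparison of two sets of
#' per-ROI period estimates: exact enumeration when the combined sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param periodsA,periodsB numeric vectors of period estimates (um),
#'   each non-empty; `NA` values are dropped.
#' @return list with components `statistic` (U for the first group) and
#'   `pValue`.
#' @examples
#' compareGroups(c(55.4, 60.1, 52.0), c(44.7, 39.6, 41.2))
#' @export
compareGroups <- function(periodsA, periodsB) {
    a <- periodsA[!is.na(periodsA)]
    b <- periodsB[!is.na(periodsB)]
    stopIfNot(length(a) >= 1 && length(b) >= 1,
              "both groups must contain at least one value")
    nTot <- length(a) + length(b)
    hasTies <- anyDuplicated(c(a, b)) > 0L
    ex <- nTot <= 20 && !hasTies
    ht <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = ex,
                           correct = TRUE))
    list(statistic = unname(ht$statistic), pValue = ht$p.value)
}
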