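# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulations so they stay independent of the
# implementations they check.

# Direct O(n^2) DFT power at positive frequencies k = 1..floor(n/2),
# I_k = |sum_t x_t exp(-2 pi i k t / n)|^2 / n.
naiveDftPower <- function(x) {
    n <- length(x)
    t <- 0:(n - 1)
    vapply(seq_len(n %/% 2), function(k) {
        re <- sum(x * cos(2 * pi * k * t / n))
        im <- sum(x * sin(2 * pi * k * t / n))
        (re^2 + im^2) / n
    }, numeric(1))
}

# Direct O(n^2) biased normalised autocorrelation at lags 0..L.
naiveAcf <- function(x, L) {
    x <- x - mean(x)
    s0 <- sum(x^2)
    vapply(0:L, function(l)
        sum(x[seq_len(length(x) - l)] * x[seq_len(length(x) - l) + l]) / s0,
        numeric(1))
}

# Monte-Carlo permutation two-tailed p-value for the Mann-Whitney U
# statistic (counts permutations at least as extreme in |U - E[U]|).
permutationUTest <- function(a, b, nPerm = 40000, seed = 1) {
    nA <- length(a); nB <- length(b)
    pooled <- c(a, b)
    uStat <- function(xa, xb) sum(rank(c(xa, xb))[seq_along(xa)]) -
        nA * (nA + 1) / 2
    obs <- abs(uStat(a, b) - nA * nB / 2)
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPerm)) {
        idx <- sample.int(nA + nB, nA)
        u <- abs(uStat(pooled[idx], pooled[-idx]) - nA * nB / 2)
        if (u >= obs - 1e-9) hits <- hits + 1L
    }
    hits / nPerm
}

# Least-squares amplitude of the sinusoidal component of period T in an
# evenly sampled signal (positions in the same units as T).
sinusoidAmplitude <- function(values, positions, T) {
    X <- cbind(1, sin(2 * pi * positions / T), cos(2 * pi * positions / T))
    cf <- stats::lm.fit(X, values)$coefficients
    unname(sqrt(cf[2]^2 + cf[3]^2))
}

# A small detrended synthetic profile used by several tests.
makeTissueProfile <- function(seed, params = tissueImageParams(seed = seed),
                              sigmaUm = 3, order = 4) {
    out <- genTissueImage(params)
    detrendProfile(rowMeanProfile(blurImage(out$image, sigmaUm)), order)
}
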