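---
title: "Measuring spatial periodicity and protrusion reach in neuroepithelia"
author: "spinecyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial periodicity and protrusion reach in neuroepithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecyto)
```

## The biological question

In the embryonic spinal cord, neural progenitors (radial glial cells,
RGCs) express the Notch target HES5 in microclusters: groups of
neighbouring cells with correlated expression that alternate high and
low along the dorsoventral (DV) axis, giving a spatial period of roughly
3–5 cell diameters (~30–50 µm at ~10 µm internuclear spacing) rather
than the 2-cell "salt and pepper" period of classical lateral
inhibition. Such longer periods require Notch/Delta signalling to reach
beyond immediate neighbours, and thin actin-based protrusions
(cytonemes) carrying DLL1 are candidates for that extended reach.

This package implements the two quantitative halves of that
investigation:

1. a **spatial-period pipeline** that reads the dominant DV period of a
   fluorescence image and its statistical support, and
2. **protrusion morphometry** — lengths, apicobasal angles, densities,
   time-lapse dynamics, ligand puncta — plus an **idealised packing
   model** that converts measured cell widths into the reach a
   protrusion needs to contact a non-neighbouring ("distal") cell.

Seeded synthetic generators reproduce the statistical structure of both
data types with full ground truth, so every stage is validated without
microscopy data.

## The spatial-period pipeline

For each rectangular ROI drawn beside the ventricle (15 µm wide by
default), `runPipeline()` applies, in order:

1. **ROI extraction** (`extractRoi()`): half-open DV interval in µm,
   apicobasal width measured from the ventricular edge.
2. **Gaussian blur** (`blurImage()`, σ = 3 µm): a sinusoid of period
   $T$ is attenuated by the transfer factor
   $\exp(-2\pi^2\sigma^2/T^2)$, i.e. to 17% at $T = 10$ µm (the
   internuclear spacing) but only to 89% at $T = 40$ µm, so the blur
   removes the influence of the gaps between nuclei while barely
   touching the microcluster period. The blur is applied to the 2D ROI
   raster before averaging, isotropically, with reflective boundary
   handling; it is implemented as frequency-domain filtering of the
   symmetrically extended signal with the exact Gaussian transfer
   function, which keeps the attenuation curve exact on the sampling
   grid (a truncated sampled kernel deviates by several percent at
   $T \approx 3\sigma$).
3. **Row-mean profile** (`rowMeanProfile()`): one intensity per DV row.
4. **Polynomial detrending** (`detrendProfile()`, order 4): removes the
   smooth intensity falloff at the expression-domain edges. Positions
   are centred on the ROI midpoint before fitting to condition the
   order-4 fit.
5. **Period estimation**, by two methods described next.

### FFT readout and the Fisher g-test

`periodogram()` computes $I_k = |X_k|^2/n$ at $k = 1..\lfloor n/2
\rfloor$ with no zero-padding, so reported periods are exactly
$n\,\Delta x/k$. `fftDominantPeriod()` reports the period of the
maximum-power ordinate, with two deterministic rules: the $k = 1$
ordinate (period = full span) is never reported, guarding against
residual trend leakage, and power ties resolve to the largest period.

Significance uses the Fisher g statistic
$g = \max_k w_k I_k / \sum_k w_k I_k$ with the exact null tail

$$p = \sum_{j=1}^{\lfloor 1/g\rfloor} (-1)^{j-1}\binom{m}{j}(1-jg)^{m-1},$$

computed on the log scale for stability. For even-length profiles the
Nyquist ordinate has one degree of freedom instead of two; it enters
the sum with weight $w = 1/2$ and $m$ counts it as one ordinate. This
is an approximation only at the Nyquist frequency; for odd lengths the
classical null is exact, and the type-I error check in the test suite
(2000 white-noise profiles of odd length) confirms the 5% size. A
non-significant estimate still carries its period, with the flag set —
downstream filtering is the caller's decision.

### ACF readout and the permutation-bootstrap envelope

`autocorrelation()` uses the biased, lag-0-normalised estimator
($r(0)=1$, $|r|\le1$) and restricts lags to $n/2$ samples, beyond which
too few pairs remain. `bootstrapAcfThreshold()` builds the per-lag null
envelope by permuting the detrended profile values (shuffling without
replacement destroys all serial structure while keeping the marginal
distribution) and taking the one-sided upper $(1-\alpha)$ quantile of
the resampled ACF at each lag, over `nBoot = 1000` resamples by
default. The envelope is per-lag, not family-wise — it mirrors the
"grey area" display convention, and the per-lag exceedance on white
noise is calibrated at 5% in the tests.

`acfPeriod()` takes significant peaks — strict local maxima over a
3-sample neighbourhood, at positive lag, above the envelope — and
averages the spacings between consecutive peaks, counting the first
spacing from lag 0 to the first peak. Equally spaced peaks at $P, 2P,
3P$ therefore give exactly $P$. With no significant peak, no period is
returned (`NA`), which is itself informative.

Each ROI (each side, each z-slice) is treated as an independent
observation, matching how per-ROI period estimates are usually plotted
and compared. Nearby ROIs from one slice are of course correlated;
this pseudo-replication is a property of the design that we document
rather than correct.

### Comparing groups

`compareGroups()` performs the two-tailed Mann–Whitney *U* test on two
sets of per-ROI periods: exact enumeration when the pooled sample is at
most 20 without ties, otherwise the normal approximation with tie and
continuity correction. No multiple-testing correction is applied across
ROIs or experiments.

```{r pipeline-demo}
out <- genTissueImage(tissueImageParams(seed = 11))
runPipeline(out$image, list(RoiBox(0, 240, side = "left")),
            runConfig(nBoot = 300, seed = 1))
```

## Protrusion morphometry and dynamics

`traceLength()` sums segment lengths of the 3D polyline (invariant to
rigid motion). `protrusionAngle()` uses the base-to-tip chord — not the
tip tangent — and reports degrees in $[-90, 90]$ with $-90°$ apical
(towards the ventricle), $0°$ perpendicular (dorsoventral), $+90°$
basal. The side correction lives in `axisFrame()`: the apical unit
vector flips between the left and right sides of the ventricle, so a
mirrored trace reports the same angle.

Three conventions are deliberate choices where the field has no single
standard, all centralised and configurable:

- **Lifetime** is frames-observed × frame interval, so a protrusion
  seen in one 2-min frame has a 2-min lifetime. This is consistent with
  a median lifetime of 4 min at 2-min sampling; the alternative
  (first-to-last-frame span) would make single-frame lifetimes zero.
- **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7); summaries are reported as median and
  interquartile range because the length and lifetime distributions are
  strongly right-skewed.
- **Puncta** (`countDll1Puncta()`) operationalise "above background and
  well separated" as strict local maxima above the background median
  plus $k = 3$ MADs, merged when closer than 1 µm; both constants are
  configurable.

Tracks truncated by the start or end of a movie can be flagged censored
and are retained by default; `excludeOutliers()` removes tracks above
an explicit lifetime cap and logs every exclusion.

## The idealised packing model

The reach model reduces the tissue to measured mean widths: apical
endfoot 5.2 µm, radial process 1.6 µm, cell body 7.7 µm. Endfeet are
assumed to tile the apical surface (hexagonal close packing by
default, giving each cell exactly six touching neighbours — the
minimum neighbour count with no protrusions), and RGCs are assumed
straight, neither curved nor intercalated. A protrusion contacts a
distal cell when it spans one intervening structure: one endfoot width
(5.2 µm) from an endfoot, one cell body width (7.7 µm) from a process.
Counting is strictly greater than the threshold. `contactReport()`
combines the required reach with the fraction of a measured length
population exceeding it:

```{r reach-demo}
lengths <- genProtrusionLengths(protrusionPopParams(n = 5000, seed = 2))
contactReport(lengths)
```

## What the synthetic data emulate — and what they do not

`genTissueImage()` renders nuclei as isotropic Gaussian bumps
(sd 2.5 µm — only their spacing matters to the pipeline) on an exact
lattice at 10 µm spacing, modulates nuclear intensity along DV with a
raised-cosine microcluster envelope (period 4 cells = 40 µm by default,
contrast 0.5; the raised cosine is smooth and adds no harmonics that
would bias the FFT readout), adds an order-2 polynomial domain trend
vanishing at the edges (the pipeline detrends with order 4, so recovery
must be insensitive to the trend order) and i.i.d. Gaussian noise at
10% of the bump amplitude. Ground truth (the cluster period) is
returned with every image.

Protrusion populations are log-normal, matched to a requested median
and interquartile range through the quantile function, which inverts in
closed form: $\mu = \log(\mathrm{median})$ and $\sigma =
\operatorname{asinh}\!\big(\mathrm{iqr}/(2\,\mathrm{median})\big) /
z_{0.75}$. The log-normal is our choice — it reproduces the strong
right skew of measured length distributions — not an established fact
about protrusions; the same applies to lifetimes. Time-lapse tracks
draw a maximum length and a lifetime per protrusion, quantise the
lifetime to the 2-min frame interval, and follow a triangular
extend-then-retract length profile peaking exactly at the drawn
maximum, so dynamics recovery can be asserted exactly.

The generator deliberately omits: the microscope PSF and z-blur,
photobleaching, nuclear position jitter, per-cell expression
variability, curved or intercalated cells, and any simulation of Notch
signalling dynamics. Two consequences matter when interpreting green
tests. First, passing period recovery shows the pipeline's numerics
are correct under the assumed structure, not that real tissue is
periodic. Second, because synthetic nuclei are equally bright on an
exact lattice, the internuclear 10 µm component is a coherent spectral
line far above the noise floor; blurring attenuates signal and noise
identically at any one frequency, so on a cluster-free synthetic image
the g-test still flags the residual 10 µm line as significant. In real
tissue, nuclear brightness and spacing vary and the internuclear
component behaves like structured noise. The blur's documented purpose
— preventing sub-cluster periodicity from *dominating* the reported
period — is what we verify: with both 10 µm and 40 µm components
present, the dominant period flips from 10 µm (no blur) to 40 µm
(σ = 3 µm).

## Numerical and design choices

- **Determinism**: every stochastic step takes an explicit seed and
  restores the global RNG state; `runPipeline()` uses one config seed
  for all ROIs, so identical ROIs give identical rows, and results
  files embed the full configuration as `#` header comments.
- **Degenerate inputs** are signalled as typed conditions, not guessed
  at: an all-zero spectrum (g undefined), a zero-variance profile (ACF
  undefined), a zero-length chord (angle undefined), a missing pixel
  calibration (never silently defaulted).
- **Validation sizes**: the test suite and acceptance script use 50
  synthetic images for period recovery (true period 40 µm over a
  240 µm domain), 2000 white-noise profiles for the g-test size, 40
  profiles × 64 lags × 1000 resamples for the envelope calibration,
  and 5000 tracks / 10^5 lengths for population recovery — sizes at
  which the binomial noise on each checked rate is comfortably inside
  the asserted bands.
- **Oracles**: the periodogram and ACF are checked against direct
  $O(n^2)$ implementations, the blur against its closed-form transfer
  function, the g-test against a Monte-Carlo exponential-spectrum
  null, and the rank test against a brute-force permutation test.

## Known limitations

- The ACF readout occasionally admits a spurious short-lag peak (the
  envelope is per-lag at 5%, so about one lag in twenty exceeds it by
  chance); because the first spacing is counted from lag 0, one early
  false peak drags the averaged period down. At the study conditions
  this leaves period recovery at 86–92% of replicates within 15%,
  rather than 100%: the FFT readout is the more robust of the two on
  clean periodic signals, which is also the behaviour seen with the
  method on real images.
- The Nyquist half-weight in the g-test is exact in the sum but
  approximate in the ordinate count $m$; use odd-length profiles where
  exactness matters.
- The packing model is a 2D idealisation of a pseudostratified 3D
  epithelium; it gives a lower bound on neighbour count and makes no
  probabilistic statement about where protrusions originate.
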