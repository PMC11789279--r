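#' @import methods
NULL

#' Calibrated 2D intensity image
#'
#' An `ImageGrid` holds a single-channel fluorescence raster with isotropic
#' micrometre calibration. By convention rows run along the dorsoventral
#' (DV) axis of the tissue and columns along the apicobasal (AB) axis, so
#' a row-mean collapses the apicobasal extent into one DV intensity
#' profile.
#'
#' @slot values numeric matrix of intensities (rows = DV, columns = AB).
#' @slot pixelUm positive scalar, micrometres per pixel (isotropic).
#'
#' @seealso [ImageGrid()], [extractRoi()], [blurImage()], [rowMeanProfile()]
#' @export
setClass("ImageGrid",
    representation(values = "matrix", pixelUm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@pixelUm) != 1L || !is.finite(object@pixelUm) ||
            object@pixelUm <= 0)
            msg <- c(msg, "'pixelUm' must be a single positive number")
        if (!is.numeric(object@values) || length(object@values) == 0L)
            msg <- c(msg, "'values' must be a non-empty numeric matrix")
        if (is.null(msg)) TRUE else msg
    })

#' Rectangular analysis region along the dorsoventral axis
#'
#' A `RoiBox` describes one rectangular region of interest on one side of
#' the ventricle: a dorsoventral interval (half-open, in micrometres) and
#' an apicobasal width measured from the ventricular edge. The default
#' 15 um width matches the analysis boxes drawn next to the ventricle.
#'
#' @slot dvStartUm,dvEndUm DV extent in micrometres, `[dvStartUm, dvEndUm)`.
#' @slot widthUm apicobasal width in micrometres (default 15).
#' @slot side `"left"` or `"right"` of the ventricle.
#' @slot zIndex 0-based z-slice index the box was drawn on.
#'
#' @seealso [RoiBox()], [extractRoi()]
#' @export
setClass("RoiBox",
    representation(dvStartUm = "numeric", dvEndUm = "numeric",
                   widthUm = "numeric", side = "character",
                   zIndex = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@dvEndUm <= object@dvStartUm)
            msg <- c(msg, "'dvEndUm' must exceed 'dvStartUm'")
        if (object@widthUm <= 0)
            msg <- c(msg, "'widthUm' must be positive")
        if (!object@side %in% c("left", "right"))
            msg <- c(msg, "'side' must be \"left\" or \"right\"")
        if (is.null(msg)) TRUE else msg
    })

#' Evenly sampled 1D intensity profile
#'
#' A `Profile1D` is an intensity-versus-dorsoventral-position signal with a
#' fixed sample spacing in micrometres, the object passed between the
#' detrending and period-estimation stages.
#'
#' @slot values numeric vector of intensities.
#' @slot spacingUm positive scalar, micrometres per sample.
#'
#' @seealso [Profile1D()], [detrendProfile()], [periodogram()],
#'   [autocorrelation()]
#' @export
setClass("Profile1D",
    representation(values = "numeric", spacingUm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@spacingUm) != 1L || !is.finite(object@spacingUm) ||
            object@spacingUm <= 0)
            msg <- c(msg, "'spacingUm' must be a single positive number")
        if (length(object@values) < 2L)
            msg <- c(msg, "profile must have at least 2 samples")
        if (is.null(msg)) TRUE else msg
    })

#' Discrete periodogram of a profile
#'
#' Power at the positive Fourier frequencies k = 1..m of a detrended
#' profile (zero frequency excluded). `periodsUm` holds the period
#' n*spacing/k for each ordinate; `weights` is 1 for every ordinate except
#' a possible Nyquist ordinate (even profile length) which carries weight
#' 1/2 in the Fisher g-test sum.
#'
#' @slot periodsUm periods (um), strictly decreasing with frequency index.
#' @slot power non-negative spectral power per ordinate.
#' @slot weights per-ordinate weight used by [fisherGTest()].
#' @slot nSamples length of the analysed profile.
#' @slot spacingUm sample spacing of the analysed profile (um).
#'
#' @seealso [periodogram()], [fisherGTest()], [fftDominantPeriod()]
#' @export
setClass("PeriodogramResult",
    representation(periodsUm = "numeric", power = "numeric",
                   weights = "numeric", nSamples = "integer",
                   spacingUm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@power) != length(object@periodsUm) ||
            length(object@weights) != length(object@power))
            msg <- c(msg, "'periodsUm', 'power', 'weights' must be equal length")
        if (any(object@power < 0))
            msg <- c(msg, "'power' must be non-negative")
        if (is.unsorted(rev(object@periodsUm), strictly = TRUE))
            msg <- c(msg, "'periodsUm' must be strictly decreasing")
        if (is.null(msg)) TRUE else msg
    })

#' Normalised autocorrelation of a profile
#'
#' Biased, lag-0-normalised autocorrelation of a detrended profile at lags
#' 0..floor(n/2) samples (longer lags are too edge-noisy to use). The
#' optional `threshold` slot holds the per-lag permutation-bootstrap
#' significance cutoff ("grey area" envelope); it is empty until attached
#' with [setAcfThreshold()].
#'
#' @slot lagsUm lags in micrometres, starting at 0.
#' @slot r autocorrelation values, `r[1] == 1`.
#' @slot threshold per-lag cutoff, same length as `r`, or empty.
#'
#' @seealso [autocorrelation()], [bootstrapAcfThreshold()], [acfPeriod()]
#' @export
setClass("AcfResult",
    representation(lagsUm = "numeric", r = "numeric", threshold = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@r) != length(object@lagsUm))
            msg <- c(msg, "'r' and 'lagsUm' must be equal length")
        if (length(object@lagsUm) && object@lagsUm[1L] != 0)
            msg <- c(msg, "lags must start at 0")
        if (length(object@r) && abs(object@r[1L] - 1) > 1e-8)
            msg <- c(msg, "r at lag 0 must be 1")
        if (any(abs(object@r) > 1 + 1e-8))
            msg <- c(msg, "|r| must not exceed 1")
        if (length(object@threshold) &&
            length(object@threshold) != length(object@r))
            msg <- c(msg, "'threshold' must be empty or match 'r' in length")
        if (is.null(msg)) TRUE else msg
    })

#' Spatial-period estimate from one profile by one method
#'
#' Result of either the periodogram ("FFT") or autocorrelation ("ACF")
#' period readout. `periodUm` is `NA` when the method found no usable
#' structure (no significant ACF peak). For the FFT method `pValue` holds
#' the Fisher g-test p-value and `significant` its comparison against the
#' chosen alpha; for the ACF method `sigPeakLagsUm` lists the significant
#' peak lags whose spacings were averaged.
#'
#' @slot method `"FFT"` or `"ACF"`.
#' @slot periodUm estimated spatial period (um), or `NA`.
#' @slot pValue Fisher g-test p-value (FFT) or `NA`.
#' @slot significant logical flag (FFT: p <= alpha; ACF: any peak).
#' @slot sigPeakLagsUm significant ACF peak lags (um); empty for FFT.
#'
#' @seealso [fftDominantPeriod()], [acfPeriod()], [runPipeline()]
#' @export
setClass("PeriodEstimate",
    representation(method = "character", periodUm = "numeric",
                   pValue = "numeric", significant = "logical",
                   sigPeakLagsUm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!object@method %in% c("FFT", "ACF"))
            msg <- c(msg, "'method' must be \"FFT\" or \"ACF\"")
        if (!is.na(object@periodUm) && object@periodUm <= 0)
            msg <- c(msg, "'periodUm' must be positive when present")
        if (!is.na(object@pValue) &&
            (object@pValue < 0 || object@pValue > 1))
            msg <- c(msg, "'pValue' must lie in [0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' A traced protrusion filament
#'
#' One protrusion trace: an ordered 3D polyline in micrometres with the
#' cell it belongs to, the side of the ventricle, and (for time-lapse
#' data) the frame time. Point 1 is the base, where the filament joins the
#' cell body.
#'
#' @slot points numeric matrix, one row per point, columns x/y/z in um.
#' @slot cellId identifier of the parent cell.
#' @slot side `"left"` or `"right"` of the ventricle.
#' @slot frameTimeMin frame time in minutes (`NA` for fixed tissue).
#' @slot baseIndex row index of the point attached to the cell body.
#'
#' @seealso [FilamentTrace()], [traceLength()], [protrusionAngle()]
#' @export
setClass("FilamentTrace",
    representation(points = "matrix", cellId = "character",
                   side = "character", frameTimeMin = "numeric",
                   baseIndex = "integer"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@points) < 2L)
            msg <- c(msg, "a trace needs at least 2 points")
        if (ncol(object@points) != 3L)
            msg <- c(msg, "'points' must have 3 columns (x, y, z in um)")
        if (nrow(object@points) >= 2L) {
            seg <- diff(object@points)
            if (any(rowSums(seg^2) == 0))
                msg <- c(msg, "consecutive points must be distinct")
        }
        if (!object@side %in% c("left", "right"))
            msg <- c(msg, "'side' must be \"left\" or \"right\"")
        if (object@baseIndex < 1L || object@baseIndex > nrow(object@points))
            msg <- c(msg, "'baseIndex' out of range")
        if (is.null(msg)) TRUE else msg
    })

#' A time-lapse protrusion track
#'
#' The time-ordered sequence of [FilamentTrace-class] snapshots of one
#' protrusion, imaged at a fixed frame interval (2 min by default, the
#' live-imaging cadence).
#'
#' @slot traces list of `FilamentTrace` objects in frame order.
#' @slot frameIntervalMin frame interval in minutes.
#' @slot censored `TRUE` if the track is truncated by the start or end of
#'   the movie (retained by default, flagged for downstream filtering).
#'
#' @seealso [ProtrusionTrack()], [trackDynamics()], [excludeOutliers()]
#' @export
setClass("ProtrusionTrack",
    representation(traces = "list", frameIntervalMin = "numeric",
                   censored = "logical"),
    validity = function(object) {
        msg <- NULL
        if (length(object@traces) < 1L)
            msg <- c(msg, "a track needs at least one frame")
        if (!all(vapply(object@traces, is, logical(1), "FilamentTrace")))
            msg <- c(msg, "'traces' must all be FilamentTrace objects")
        if (object@frameIntervalMin <= 0)
            msg <- c(msg, "'frameIntervalMin' must be positive")
        tms <- vapply(object@traces, function(t) t@frameTimeMin, numeric(1))
        if (length(tms) > 1L && !all(is.na(tms))) {
            d <- diff(tms)
            if (any(d <= 0) ||
                any(abs(d - object@frameIntervalMin) > 1e-6))
                msg <- c(msg, paste0("frame times must increase in uniform ",
                                     "steps of 'frameIntervalMin'"))
        }
        if (is.null(msg)) TRUE else msg
    })

#' Tissue axis frame for angle measurement
#'
#' Defines the local coordinate frame used to measure protrusion angles:
#' a unit apicobasal direction with its apical sense pointing towards the
#' ventricle, and an orthogonal unit dorsoventral direction. Because the
#' ventricle lies between the two halves of the neuroepithelium, the
#' apical direction flips between the left and right sides; constructing
#' the frame per side applies that correction so that -90 deg always
#' means "towards the ventricle".
#'
#' @slot apicalDir unit 3-vector pointing apically (towards the ventricle).
#' @slot dvDir unit 3-vector along the dorsoventral axis.
#' @slot side `"left"` or `"right"`.
#'
#' @seealso [axisFrame()], [protrusionAngle()]
#' @export
setClass("AxisFrame",
    representation(apicalDir = "numeric", dvDir = "numeric",
                   side = "character"),
    validity = function(object) {
        msg <- NULL
        if (abs(sum(object@apicalDir^2) - 1) > 1e-8 ||
            abs(sum(object@dvDir^2) - 1) > 1e-8)
            msg <- c(msg, "direction vectors must be unit length")
        if (abs(sum(object@apicalDir * object@dvDir)) > 1e-8)
            msg <- c(msg, "directions must be orthogonal")
        if (!object@side %in% c("left", "right"))
            msg <- c(msg, "'side' must be \"left\" or \"right\"")
        if (is.null(msg)) TRUE else msg
    })
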