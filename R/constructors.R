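#' Construct an ImageGrid
#'
#' @param values numeric matrix of intensities; rows are dorsoventral
#'   positions, columns apicobasal positions.
#' @param pixelUm micrometres per pixel (isotropic).
#' @return An [ImageGrid-class] object.
#' @examples
#' img <- ImageGrid(matrix(rnorm(80), nrow = 10), pixelUm = 1)
#' img
#' @export
ImageGrid <- function(values, pixelUm) {
    if (!is.matrix(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("ImageGrid", values = values, pixelUm = as.numeric(pixelUm))
}

#' Construct a RoiBox
#'
#' @param dvStartUm,dvEndUm dorsoventral extent in micrometres (half-open
#'   interval).
#' @param widthUm apicobasal box width in micrometres (default 15, the
#'   width of the analysis boxes drawn along the ventricle).
#' @param side `"left"` or `"right"` of the ventricle.
#' @param zIndex 0-based z-slice index.
#' @return A [RoiBox-class] object.
#' @examples
#' RoiBox(0, 120, side = "left")
#' @export
RoiBox <- function(dvStartUm, dvEndUm, widthUm = 15, side = "left",
                   zIndex = 0L) {
    new("RoiBox", dvStartUm = as.numeric(dvStartUm),
        dvEndUm = as.numeric(dvEndUm), widthUm = as.numeric(widthUm),
        side = side, zIndex = as.integer(zIndex))
}

#' Construct a Profile1D
#'
#' @param values numeric intensity values.
#' @param spacingUm micrometres between consecutive samples.
#' @return A [Profile1D-class] object.
#' @examples
#' Profile1D(sin(2 * pi * (0:99) / 25), spacingUm = 1)
#' @export
Profile1D <- function(values, spacingUm) {
    new("Profile1D", values = as.numeric(values),
        spacingUm = as.numeric(spacingUm))
}

#' Construct a FilamentTrace
#'
#' @param points numeric matrix (or data.frame) with one row per point and
#'   columns x, y, z in micrometres, ordered from the base outwards.
#' @param cellId identifier of the parent cell.
#' @param side `"left"` or `"right"` of the ventricle.
#' @param frameTimeMin frame time in minutes; `NA` for fixed tissue.
#' @param baseIndex row index of the base point (default 1).
#' @return A [FilamentTrace-class] object.
#' @examples
#' FilamentTrace(rbind(c(0, 0, 0), c(3, 4, 0)), cellId = "c1")
#' @export
FilamentTrace <- function(points, cellId = "cell", side = "left",
                          frameTimeMin = NA_real_, baseIndex = 1L) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    colnames(points) <- c("x", "y", "z")
    new("FilamentTrace", points = points, cellId = as.character(cellId),
        side = side, frameTimeMin = as.numeric(frameTimeMin),
        baseIndex = as.integer(baseIndex))
}

#' Construct a ProtrusionTrack
#'
#' @param traces list of [FilamentTrace-class] snapshots in frame order.
#' @param frameIntervalMin frame interval in minutes (default 2).
#' @param censored logical; `TRUE` if truncated by movie start/end.
#' @return A [ProtrusionTrack-class] object.
#' @export
ProtrusionTrack <- function(traces, frameIntervalMin = 2,
                            censored = FALSE) {
    new("ProtrusionTrack", traces = traces,
        frameIntervalMin = as.numeric(frameIntervalMin),
        censored = censored)
}

#' Construct a tissue axis frame for one side of the ventricle
#'
#' The default geometry follows the imaging convention in which the
#' x-axis is apicobasal and the y-axis dorsoventral (lined up along the
#' ventricle). Apical means "towards the ventricle", so the apical unit
#' vector points in +x on the left side and -x on the right side; angles
#' measured with the resulting frame are side-corrected automatically.
#'
#' @param side `"left"` or `"right"` of the ventricle.
#' @param apicalDir,dvDir optional explicit unit direction vectors that
#'   override the default geometry (e.g. for rotated acquisitions).
#' @return An [AxisFrame-class] object.
#' @examples
#' axisFrame("left")
#' axisFrame("right")
#' @export
axisFrame <- function(side = c("left", "right"), apicalDir = NULL,
                      dvDir = NULL) {
    side <- match.arg(side)
    if (is.null(apicalDir))
        apicalDir <- if (side == "left") c(1, 0, 0) else c(-1, 0, 0)
    if (is.null(dvDir)) dvDir <- c(0, 1, 0)
    new("AxisFrame", apicalDir = as.numeric(apicalDir),
        dvDir = as.numeric(dvDir), side = side)
}

## ---- accessors ----

#' Accessors for spinecyto objects
#'
#' `intensityValues()` returns the raster matrix of an [ImageGrid-class];
#' `pixelSize()` its micrometre calibration. `profileValues()` and
#' `sampleSpacing()` are the analogues for [Profile1D-class].
#' `tracePoints()` returns the point matrix of a [FilamentTrace-class].
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases intensityValues pixelSize profileValues sampleSpacing
#'   tracePoints
#' @examples
#' p <- Profile1D(rnorm(32), spacingUm = 0.5)
#' length(profileValues(p))
#' sampleSpacing(p)
NULL

#' @rdname accessors
#' @export
intensityValues <- function(x) x@values

#' @rdname accessors
#' @export
pixelSize <- function(x) x@pixelUm

#' @rdname accessors
#' @export
profileValues <- function(x) x@values

#' @rdname accessors
#' @export
sampleSpacing <- function(x) x@spacingUm

#' @rdname accessors
#' @export
tracePoints <- function(x) x@points

## ---- show methods ----

setMethod("show", "ImageGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("ImageGrid: %d x %d px at %.3g um/px (%.4g x %.4g um)\n",
                d[1L], d[2L], object@pixelUm,
                d[1L] * object@pixelUm, d[2L] * object@pixelUm))
})

setMethod("show", "RoiBox", function(object) {
    cat(sprintf("RoiBox: DV [%.4g, %.4g) um, width %.4g um, %s side, z=%d\n",
                object@dvStartUm, object@dvEndUm, object@widthUm,
                object@side, object@zIndex))
})

setMethod("show", "Profile1D", function(object) {
    cat(sprintf("Profile1D: %d samples at %.3g um (span %.4g um)\n",
                length(object@values), object@spacingUm,
                length(object@values) * object@spacingUm))
})

setMethod("show", "PeriodogramResult", function(object) {
    k <- which.max(object@power)
    cat(sprintf("PeriodogramResult: %d ordinates; top period %.4g um\n",
                length(object@power), object@periodsUm[k]))
})

setMethod("show", "AcfResult", function(object) {
    cat(sprintf("AcfResult: lags 0..%.4g um (%d), threshold %s\n",
                max(object@lagsUm), length(object@r),
                if (length(object@threshold)) "attached" else "not set"))
})

setMethod("show", "PeriodEstimate", function(object) {
    cat(sprintf("PeriodEstimate [%s]: period %s um%s%s\n",
                object@method,
                if (is.na(object@periodUm)) "NA"
                else sprintf("%.4g", object@periodUm),
                if (!is.na(object@pValue))
                    sprintf(", Fisher g p = %.3g", object@pValue) else "",
                if (object@method == "ACF")
                    sprintf(", %d significant peak(s)",
                            length(object@sigPeakLagsUm)) else ""))
})

setMethod("show", "FilamentTrace", function(object) {
    cat(sprintf("FilamentTrace: %d points, %.4g um, cell %s (%s side)%s\n",
                nrow(object@points), traceLength(object), object@cellId,
                object@side,
                if (is.na(object@frameTimeMin)) ""
                else sprintf(", t = %g min", object@frameTimeMin)))
})

setMethod("show", "ProtrusionTrack", function(object) {
    cat(sprintf("ProtrusionTrack: %d frames at %g min%s\n",
                length(object@traces), object@frameIntervalMin,
                if (object@censored) " (censored)" else ""))
})

setMethod("show", "AxisFrame", function(object) {
    cat(sprintf("AxisFrame (%s side): apical -> (%g, %g, %g)\n",
                object@side, object@apicalDir[1L], object@apicalDir[2L],
                object@apicalDir[3L]))
})
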