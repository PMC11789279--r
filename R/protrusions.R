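#' Protrusion trace length
#'
#' Length of a traced filament as the summed Euclidean length of its
#' segments.
#'
#' @param t a [FilamentTrace-class].
#' @return length in micrometres.
#' @examples
#' traceLength(FilamentTrace(rbind(c(0, 0, 0), c(3, 4, 0))))   # 5
#' @export
traceLength <- function(t) {
    stopifnot(is(t, "FilamentTrace"))
    sum(sqrt(rowSums(diff(t@points)^2)))
}

#' Protrusion angle relative to the apicobasal axis
#'
#' Computed from the base-to-tip chord of the trace: the angle is
#' `atan2(basal component, |dorsoventral component|)` in degrees, so 0
#' means perpendicular to the apicobasal axis (pointing along the
#' dorsoventral axis), -90 means pointing apically (towards the
#' ventricle) and +90 basally. The side correction is carried by the
#' [axisFrame()]: its apical direction flips between the left and right
#' sides of the ventricle so mirrored traces report the same angle.
#'
#' @param t a [FilamentTrace-class] whose first point is the base.
#' @param frame an [AxisFrame-class] matching the trace's side.
#' @return angle in degrees, in `[-90, 90]`.
#' @examples
#' fr <- axisFrame("left")
#' protrusionAngle(FilamentTrace(rbind(c(0, 0, 0), c(0, 5, 0))), fr)  # 0
#' protrusionAngle(FilamentTrace(rbind(c(0, 0, 0), c(5, 0, 0))), fr)  # -90
#' @export
protrusionAngle <- function(t, frame) {
    stopifnot(is(t, "FilamentTrace"), is(frame, "AxisFrame"))
    if (frame@side != t@side)
        warning("axis frame side does not match trace side")
    chord <- t@points[nrow(t@points), ] - t@points[t@baseIndex, ]
    if (sum(chord^2) == 0)
        stop(errorCondition("zero-length chord: angle undefined",
                            class = c("spinecyto_degenerate_error",
                                      "error", "condition")))
    basal <- -sum(chord * frame@apicalDir)      # positive away from ventricle
    dv <- sum(chord * frame@dvDir)
    atan2(basal, abs(dv)) * 180 / pi
}

#' Protrusion density along a cell
#'
#' Number of protrusions associated with a cell divided by the traced
#' apicobasal path length of that cell, in protrusions per micrometre.
#'
#' @param nProtrusions number of protrusions attached to the cell.
#' @param pathLengthUm traced cell length in micrometres (> 0).
#' @return density in protrusions per um.
#' @examples
#' protrusionDensity(10, 50)   # 0.2
#' @export
protrusionDensity <- function(nProtrusions, pathLengthUm) {
    stopIfNot(pathLengthUm > 0, "'pathLengthUm' must be positive")
    stopIfNot(nProtrusions >= 0, "'nProtrusions' must be non-negative")
    nProtrusions / pathLengthUm
}

#' Time-lapse dynamics of one protrusion track
#'
#' The maximum extension is the largest per-frame trace length; the
#' lifetime is the number of frames the protrusion was observed times
#' the frame interval, so a protrusion seen in a single 2-minute frame
#' has a 2-minute lifetime (consistent with a 4 min median lifetime at
#' 2 min sampling). The angle at maximum extension is computed on the
#' longest frame when an axis frame is supplied.
#'
#' @param tr a [ProtrusionTrack-class].
#' @param frame optional [AxisFrame-class] for the angle at maximum.
#' @return list with `maxLengthUm`, `lifetimeMin` and `angleAtMaxDeg`
#'   (`NA` without a frame).
#' @examples
#' tracks <- genTimelapseTracks(protrusionPopParams(n = 1, seed = 9))
#' trackDynamics(tracks$tracks[[1]])
#' @export
trackDynamics <- function(tr, frame = NULL) {
    stopifnot(is(tr, "ProtrusionTrack"))
    lens <- vapply(tr@traces, traceLength, numeric(1))
    iMax <- which.max(lens)
    ang <- if (is.null(frame)) NA_real_
           else protrusionAngle(tr@traces[[iMax]], frame)
    list(maxLengthUm = lens[iMax],
         lifetimeMin = length(tr@traces) * tr@frameIntervalMin,
         angleAtMaxDeg = ang)
}

#' Median and interquartile-range summary
#'
#' The summary convention used for all morphometry: median and
#' `Q3 - Q1` with linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector (`NA` dropped; at least one value).
#' @return list with `median`, `iqr` and `n`.
#' @examples
#' summariseMedianIqr(1:5)   # median 3, iqr 2
#' @export
summariseMedianIqr <- function(values) {
    values <- values[!is.na(values)]
    stopIfNot(length(values) >= 1, "need at least one value")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                         type = 7)
    list(median = q[2L], iqr = q[3L] - q[1L], n = length(values))
}

#' Exclude tracks with outlier lifetimes
#'
#' Removes tracks whose lifetime exceeds the cap (e.g. a single
#' protrusion persisting 150 min in an otherwise ~4 min population) and
#' logs every exclusion with its reason. Re-running on the filtered
#' output is idempotent.
#'
#' @param tracks list of [ProtrusionTrack-class].
#' @param lifetimeCapMin lifetime cap in minutes (> 0; `Inf` keeps all).
#' @return list with `tracks` (retained) and `exclusions` (data.frame
#'   with columns `index`, `lifetime_min`, `reason`).
#' @examples
#' tracks <- genTimelapseTracks(protrusionPopParams(n = 20, seed = 1))
#' excludeOutliers(tracks$tracks, lifetimeCapMin = 100)
#' @export
excludeOutliers <- function(tracks, lifetimeCapMin) {
    stopIfNot(lifetimeCapMin > 0, "'lifetimeCapMin' must be positive")
    lt <- vapply(tracks, function(tr)
        length(tr@traces) * tr@frameIntervalMin, numeric(1))
    drop <- which(lt > lifetimeCapMin)
    exclusions <- data.frame(
        index = drop, lifetime_min = lt[drop],
        reason = if (length(drop))
            sprintf("lifetime %g min exceeds cap %g min", lt[drop],
                    lifetimeCapMin) else character(0))
    list(tracks = if (length(drop)) tracks[-drop] else tracks,
         exclusions = exclusions)
}

#' Count well-separated ligand puncta along a trace
#'
#' Counts DLL1-like puncta as strict local intensity maxima along the
#' trace that (i) exceed the background median plus `k` robust standard
#' deviations (MAD with the consistency constant) and (ii) are separated
#' from any brighter retained punctum by at least `minSepUm`; closer
#' maxima merge into the brighter one.
#'
#' @param intensity intensity samples along the trace.
#' @param positionsUm positions of the samples along the trace (um),
#'   increasing, same length as `intensity`.
#' @param background background intensity samples (non-empty).
#' @param k threshold in MADs above the background median (default 3).
#' @param minSepUm minimum separation between puncta in um (default 1).
#' @return number of puncta.
#' @examples
#' pos <- seq(0, 10, by = 0.1)
#' prof <- exp(-(pos - 5)^2 / 0.1) * 10
#' countDll1Puncta(prof, pos, background = rnorm(50, 0, 0.1))   # 1
#' @export
countDll1Puncta <- function(intensity, positionsUm, background, k = 3,
                            minSepUm = 1) {
    stopIfNot(length(intensity) > 0 && length(background) > 0,
              "intensity and background samples must be non-empty")
    stopIfNot(length(intensity) == length(positionsUm),
              "'positionsUm' must match 'intensity' in length")
    thr <- stats::median(background) + k * stats::mad(background)
    n <- length(intensity)
    if (n < 3L) return(0L)
    i <- 2:(n - 1L)
    cand <- i[intensity[i] > intensity[i - 1L] &
              intensity[i] > intensity[i + 1L] & intensity[i] > thr]
    if (!length(cand)) return(0L)
    cand <- cand[order(intensity[cand], decreasing = TRUE)]
    kept <- numeric(0)
    for (idx in cand)
        if (!length(kept) ||
            all(abs(positionsUm[idx] - kept) >= minSepUm))
            kept <- c(kept, positionsUm[idx])
    length(kept)
}

#' Angle distributions binned by protrusion length class
#'
#' Splits protrusions into the length classes `<5`, `5-10` and `>10` um
#' (edges exactly at 5 and 10 um, right-open intervals) and histograms
#' the apicobasal angles within each class.
#'
#' @param anglesDeg protrusion angles in degrees, in `[-90, 90]`.
#' @param lengthsUm protrusion lengths in um, paired with `anglesDeg`.
#' @param angleBreaks histogram breaks for the angles (default 15-degree
#'   bins spanning -90..90).
#' @return data.frame with columns `length_class`, `angle_mid_deg`,
#'   `count`; counts sum to the number of protrusions.
#' @examples
#' angleLengthBins(c(0, -45, 80), c(4.9, 5, 10))
#' @export
angleLengthBins <- function(anglesDeg, lengthsUm,
                            angleBreaks = seq(-90, 90, by = 15)) {
    stopIfNot(length(anglesDeg) == length(lengthsUm),
              "angles and lengths must be paired")
    cls <- cut(lengthsUm, breaks = c(-Inf, 5, 10, Inf), right = FALSE,
               labels = c("<5", "5-10", ">10"))
    mids <- (angleBreaks[-1] + angleBreaks[-length(angleBreaks)]) / 2
    out <- lapply(levels(cls), function(lv) {
        a <- anglesDeg[cls == lv]
        counts <- if (length(a))
            graphics::hist(a, breaks = angleBreaks, plot = FALSE,
                           include.lowest = TRUE)$counts
        else rep(0L, length(mids))
        data.frame(length_class = lv, angle_mid_deg = mids,
                   count = counts)
    })
    do.call(rbind, out)
}
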