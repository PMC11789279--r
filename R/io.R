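#' Run configuration for the analysis pipeline
#'
#' Collects every tunable parameter with its default: 3 um blur, order-4
#' detrend, alpha 0.05, 1000 bootstrap resamples, 15 um ROI width, the
#' puncta detection constants and the lifetime outlier cap. The
#' effective configuration travels with every results file (as `#`
#' header comments) so each run is reproducible.
#'
#' @param sigmaUm Gaussian blur sd in um (default 3).
#' @param polyOrder detrending polynomial order (default 4).
#' @param alpha significance level (default 0.05).
#' @param nBoot bootstrap resamples for the ACF threshold (default 1000).
#' @param seed RNG seed governing all stochastic steps (default 1).
#' @param roiWidthUm default ROI width in um (default 15).
#' @param pixelUm optional pixel-size override for images without
#'   calibration metadata (`NA` = require metadata).
#' @param punctaK puncta threshold in background MADs (default 3).
#' @param punctaMinSepUm minimum puncta separation in um (default 1).
#' @param lifetimeCapMin lifetime outlier cap in minutes (default `Inf`).
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(sigmaUm = 3, polyOrder = 4, alpha = 0.05,
                      nBoot = 1000, seed = 1, roiWidthUm = 15,
                      pixelUm = NA_real_, punctaK = 3,
                      punctaMinSepUm = 1, lifetimeCapMin = Inf) {
    stopIfNot(sigmaUm >= 0, "'sigmaUm' must be non-negative")
    stopIfNot(polyOrder >= 1, "'polyOrder' must be at least 1")
    stopIfNot(alpha > 0 && alpha < 1, "'alpha' must lie in (0, 1)")
    stopIfNot(nBoot >= 1, "'nBoot' must be positive")
    structure(list(sigmaUm = sigmaUm, polyOrder = polyOrder,
                   alpha = alpha, nBoot = nBoot, seed = seed,
                   roiWidthUm = roiWidthUm, pixelUm = pixelUm,
                   punctaK = punctaK, punctaMinSepUm = punctaMinSepUm,
                   lifetimeCapMin = lifetimeCapMin),
              class = "RunConfig")
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [runConfig()] list.
#' @return `readConfig` returns a `RunConfig`; `writeConfig` the path,
#'   invisibly.
#' @rdname configIo
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        warning("ignoring unknown config keys: ",
                paste(unknown, collapse = ", "))
    do.call(runConfig, vals[intersect(names(vals), known)])
}

#' @rdname configIo
#' @export
writeConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    vals <- unclass(config)
    vals <- lapply(vals, function(v) if (is.infinite(v)) ".inf" else v)
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' Read a calibrated single-channel TIFF image
#'
#' Loads the raster and its micrometre calibration. The pixel size is
#' taken from a sidecar YAML (`<path>.yaml`, written by
#' [writeImageTiff()]) when present, else from `config$pixelUm`;
#' a missing calibration is an error, never a silent default.
#'
#' @param path TIFF file path (8/16-bit, single channel).
#' @param config optional [runConfig()] supplying a `pixelUm` override.
#' @return An [ImageGrid-class].
#' @export
readImageTiff <- function(path, config = runConfig()) {
    raw <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    sidecar <- paste0(path, ".yaml")
    meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
    px <- if (!is.null(meta$pixel_um)) meta$pixel_um
          else if (!is.na(config$pixelUm)) config$pixelUm
          else stop(errorCondition(
              paste0("no pixel calibration: provide a '", basename(sidecar),
                     "' sidecar or a config pixelUm override"),
              class = c("spinecyto_calibration_error", "error",
                        "condition")))
    scale <- if (!is.null(meta$intensity_max)) meta$intensity_max else 1
    ImageGrid(raw * scale, px)
}

#' Write a calibrated image as 16-bit TIFF with a YAML sidecar
#'
#' Intensities are scaled into `[0, 1]` for the 16-bit TIFF; the scale
#' (`intensity_max`) and the pixel size (`pixel_um`) are recorded in a
#' `<path>.yaml` sidecar so [readImageTiff()] restores both.
#'
#' @param image an [ImageGrid-class].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(image, path) {
    stopifnot(is(image, "ImageGrid"))
    v <- image@values
    v <- pmax(v, 0)
    mx <- max(v)
    if (mx == 0) mx <- 1
    tiff::writeTIFF(v / mx, path, bits.per.sample = 16L)
    yaml::write_yaml(list(pixel_um = image@pixelUm, intensity_max = mx),
                     paste0(path, ".yaml"))
    invisible(path)
}

#' Read filament traces and tracks from CSV
#'
#' Expects one point per row with columns `trace_id`, `cell_id`, `side`,
#' `frame_time_min`, `point_index`, `x_um`, `y_um`, `z_um` (the export
#' schema for semi-automatically traced filaments). Rows may be in any
#' order; points are restored by `point_index` and frames by
#' `frame_time_min`. Traces sharing a `trace_id` across frames are
#' assembled into [ProtrusionTrack-class] objects; traces without frame
#' times load as fixed-tissue [FilamentTrace-class] objects.
#'
#' @param path CSV file path.
#' @param frameIntervalMin frame interval for assembled tracks (default
#'   2 min).
#' @return list with `traces` (single-frame [FilamentTrace-class]s,
#'   named by trace id) and `tracks` (multi-frame
#'   [ProtrusionTrack-class]s, named by trace id).
#' @export
readTraces <- function(path, frameIntervalMin = 2) {
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    needed <- c("trace_id", "cell_id", "side", "frame_time_min",
                "point_index", "x_um", "y_um", "z_um")
    missing <- setdiff(needed, names(df))
    if (length(missing))
        stop(errorCondition(
            paste0("trace CSV is missing column(s): ",
                   paste(missing, collapse = ", ")),
            class = c("spinecyto_format_error", "error", "condition")))
    key <- paste(df$trace_id, df$frame_time_min, df$point_index)
    if (anyDuplicated(key))
        stop(errorCondition(
            "duplicate (trace_id, frame_time_min, point_index) rows",
            class = c("spinecyto_format_error", "error", "condition")))
    traces <- list(); tracks <- list()
    for (id in unique(df$trace_id)) {
        sub <- df[df$trace_id == id, ]
        frames <- sort(unique(sub$frame_time_min))
        mk <- function(tm) {
            pts <- sub[sub$frame_time_min == tm |
                       (is.na(tm) & is.na(sub$frame_time_min)), ]
            pts <- pts[order(pts$point_index), ]
            FilamentTrace(as.matrix(pts[, c("x_um", "y_um", "z_um")]),
                          cellId = pts$cell_id[1L], side = pts$side[1L],
                          frameTimeMin = tm)
        }
        if (all(is.na(sub$frame_time_min))) {
            traces[[as.character(id)]] <- mk(NA_real_)
        } else if (length(frames) == 1L) {
            traces[[as.character(id)]] <- mk(frames)
        } else {
            d <- diff(frames)
            if (any(d <= 0) || any(abs(d - d[1L]) > 1e-6))
                stop(errorCondition(
                    sprintf("trace %s: frame times not uniformly increasing",
                            id),
                    class = c("spinecyto_format_error", "error",
                              "condition")))
            tracks[[as.character(id)]] <- ProtrusionTrack(
                lapply(frames, mk), frameIntervalMin = d[1L])
        }
    }
    list(traces = traces, tracks = tracks)
}

#' Write filament traces/tracks to the CSV trace schema
#'
#' @param traces named list of [FilamentTrace-class] and/or
#'   [ProtrusionTrack-class] objects; names become trace ids.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTraces <- function(traces, path) {
    rows <- list()
    for (id in names(traces)) {
        obj <- traces[[id]]
        tl <- if (is(obj, "ProtrusionTrack")) obj@traces else list(obj)
        for (tr in tl) {
            pts <- tr@points
            rows[[length(rows) + 1L]] <- data.frame(
                trace_id = id, cell_id = tr@cellId, side = tr@side,
                frame_time_min = tr@frameTimeMin,
                point_index = seq_len(nrow(pts)),
                x_um = pts[, 1L], y_um = pts[, 2L], z_um = pts[, 3L])
        }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' Read an ROI list from CSV
#'
#' Columns: `image`, `side`, `z_index`, `dv_start_um`, `dv_end_um` and
#' optionally `width_um` (default from config). Positions in um, 0-based
#' z indices, half-open DV intervals.
#'
#' @param path CSV file path.
#' @param config a [runConfig()] supplying the default ROI width.
#' @return list of [RoiBox-class] objects with an `image` attribute per
#'   element.
#' @export
readRoiCsv <- function(path, config = runConfig()) {
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    needed <- c("image", "side", "z_index", "dv_start_um", "dv_end_um")
    missing <- setdiff(needed, names(df))
    if (length(missing))
        stop(errorCondition(
            paste0("ROI CSV is missing column(s): ",
                   paste(missing, collapse = ", ")),
            class = c("spinecyto_format_error", "error", "condition")))
    lapply(seq_len(nrow(df)), function(i) {
        w <- if ("width_um" %in% names(df) && !is.na(df$width_um[i]))
            df$width_um[i] else config$roiWidthUm
        roi <- RoiBox(df$dv_start_um[i], df$dv_end_um[i], widthUm = w,
                      side = df$side[i], zIndex = df$z_index[i])
        attr(roi, "image") <- df$image[i]
        roi
    })
}

#' Write a results table with a reproducibility header
#'
#' Writes a tidy CSV with deterministic column order, preceded by `#`
#' comment lines recording the effective configuration (including the
#' seed) so identical inputs and seed produce byte-identical files.
#'
#' @param table data.frame of results.
#' @param path output CSV path.
#' @param config the [runConfig()] used for the run.
#' @return the path, invisibly.
#' @rdname resultsIo
#' @export
writeResults <- function(table, path, config = runConfig()) {
    stopifnot(is.data.frame(table))
    con <- file(path, open = "wt")
    on.exit(close(con))
    vals <- unclass(config)
    hdr <- vapply(names(vals), function(k)
        sprintf("# %s: %s", k, format(vals[[k]], digits = 15)),
        character(1))
    writeLines(c("# spinecyto results", hdr), con)
    utils::write.csv(table[, sort(names(table)), drop = FALSE], con,
                     row.names = FALSE)
    invisible(path)
}

#' @rdname resultsIo
#' @export
readResults <- function(path) {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
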