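#' Read a calibrated TIFF image
#'
#' Reads a single-plane (or stacked) grayscale TIFF and attaches the physical
#' pixel size. The calibration is resolved in this order: an explicit
#' \code{pixelSizeOverride} always wins; otherwise the TIFF resolution tags
#' are used (interpreted as pixels per micrometre when no resolution unit is
#' recorded, and converted from pixels per cm / inch otherwise); otherwise a
#' \code{<path>.json} sidecar written by [writeCalibratedImage()] is
#' consulted. If none of these yields a pixel size the read fails loudly:
#' downstream operations are meaningless without physical units.
#'
#' Anisotropic calibrations (x and y resolution tags that disagree) are
#' rejected rather than silently averaged.
#'
#' @param path TIFF file path.
#' @param pixelSizeOverride optional pixel size in micrometres per pixel.
#' @param channelName channel label to attach.
#' @return A [CalibratedImage-class], or a list of them for a multi-plane
#'   stack.
#' @importFrom tiff readTIFF
#' @importFrom jsonlite read_json
#' @export
readCalibratedImage <- function(path, pixelSizeOverride = NULL,
                                channelName = "") {
    if (!file.exists(path))
        stop("image file not found: ", path)
    planes <- tryCatch(tiff::readTIFF(path, info = TRUE, all = TRUE),
                       error = function(e)
                           stop("unreadable TIFF '", path, "': ",
                                conditionMessage(e)))
    ps <- if (!is.null(pixelSizeOverride)) {
        as.numeric(pixelSizeOverride)
    } else {
        tagPs <- .pixelSizeFromTags(planes[[1L]])
        if (!is.null(tagPs)) tagPs else .pixelSizeFromSidecar(path)
    }
    if (is.null(ps) || !is.finite(ps) || ps <= 0)
        stop("no pixel size available for '", path,
             "': supply pixelSizeOverride, TIFF resolution tags, ",
             "or a .json sidecar")
    scale <- .scaleFromSidecar(path)
    out <- lapply(planes, function(m) {
        if (length(dim(m)) == 3L) {
            if (dim(m)[3L] == 1L) m <- m[, , 1L]
            else stop("multi-channel TIFF planes are not supported; ",
                      "split channels first")
        }
        CalibratedImage(m * scale, ps, channelName)
    })
    if (length(out) == 1L) out[[1L]] else out
}

.pixelSizeFromTags <- function(plane) {
    xr <- attr(plane, "x.resolution")
    yr <- attr(plane, "y.resolution")
    if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
    if (!is.null(yr) && is.finite(yr) && abs(yr - xr) > 1e-6 * xr)
        stop("anisotropic TIFF calibration (x.resolution != y.resolution) ",
             "is not supported")
    unit <- attr(plane, "resolution.unit")
    perUm <- switch(
        if (is.null(unit)) "none" else as.character(unit),
        "inch" = xr / 25400,
        "cm"   = xr / 1e4,
        xr  # unitless: pixels per micrometre
    )
    1 / perUm
}

.sidecarPath <- function(path) paste0(path, ".json")

.pixelSizeFromSidecar <- function(path) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) return(NULL)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$pixel_size_um)) NULL else as.numeric(meta$pixel_size_um)
}

.scaleFromSidecar <- function(path) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) return(1)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$intensity_scale)) 1 else as.numeric(meta$intensity_scale)
}

#' Write a calibrated image as TIFF plus metadata sidecar
#'
#' Intensities are stored as 32-bit float TIFF normalised to [0, 1]; the
#' normalisation factor and the pixel size go into a \code{<path>.json}
#' sidecar (the linked TIFF library cannot write resolution tags), which
#' [readCalibratedImage()] uses to restore calibrated values.
#'
#' @param image a [CalibratedImage-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @importFrom tiff writeTIFF
#' @importFrom jsonlite write_json
#' @export
writeCalibratedImage <- function(image, path) {
    stopifnot(is(image, "CalibratedImage"))
    mx <- max(image@pixels)
    scale <- if (mx > 0) mx else 1
    tiff::writeTIFF(image@pixels / scale, path, bits.per.sample = 32L,
                    compression = "none")
    jsonlite::write_json(
        list(pixel_size_um = image@pixelSize, intensity_scale = scale,
             channel = image@channelName),
        .sidecarPath(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read / write binary masks
#'
#' Masks are stored as 8-bit TIFF (0/255) with a pixel-size sidecar; the
#' round trip is lossless.
#'
#' @param path TIFF file path.
#' @param pixelSizeOverride optional pixel size in micrometres.
#' @return [readMask()]: a [MaskImage-class]; [writeMask()]: \code{path},
#'   invisibly.
#' @export
readMask <- function(path, pixelSizeOverride = NULL) {
    if (!file.exists(path))
        stop("mask file not found: ", path)
    m <- tiff::readTIFF(path, info = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    ps <- if (!is.null(pixelSizeOverride)) as.numeric(pixelSizeOverride)
          else {
              tagPs <- .pixelSizeFromTags(m)
              if (!is.null(tagPs)) tagPs else .pixelSizeFromSidecar(path)
          }
    if (is.null(ps))
        stop("no pixel size available for mask '", path, "'")
    MaskImage((m > 0.5) * 1, ps)
}

#' @rdname readMask
#' @param mask a [MaskImage-class].
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "MaskImage"))
    tiff::writeTIFF(mask@pixels, path, bits.per.sample = 8L,
                    compression = "none")
    jsonlite::write_json(list(pixel_size_um = mask@pixelSize),
                         .sidecarPath(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a polyline ROI from JSON or CSV
#'
#' JSON files hold either an array of [x, y] pairs or an object with a
#' \code{points} field; CSV files hold two columns (x, y), header optional.
#' Coordinates are micrometres. Polylines with fewer than two points, repeated
#' consecutive points, or zero arc length are rejected.
#'
#' @param path file path ending in .json, .csv or .txt.
#' @return A [PolylineROI-class].
#' @export
readPolylineROI <- function(path) {
    if (!file.exists(path))
        stop("ROI file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    pts <- if (ext == "json") {
        obj <- jsonlite::read_json(path, simplifyVector = TRUE)
        if (is.list(obj) && !is.null(obj$points)) obj <- obj$points
        m <- as.matrix(obj)
        storage.mode(m) <- "double"
        m
    } else {
        first <- readLines(path, n = 1L)
        hasHeader <- !grepl("^\\s*[-+0-9.eE]+\\s*,", first)
        as.matrix(utils::read.csv(path, header = hasHeader,
                                  col.names = c("x", "y")))
    }
    if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) < 2L)
        stop("ROI '", path, "' must contain at least 2 (x, y) points")
    tryCatch(PolylineROI(pts), error = function(e)
        stop("degenerate polyline in '", path, "': ", conditionMessage(e)))
}

#' Write a polyline ROI as JSON
#'
#' @param roi a [PolylineROI-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePolylineROI <- function(roi, path) {
    stopifnot(is(roi, "PolylineROI"))
    jsonlite::write_json(list(points = unname(apply(roi@points, 1, as.list))),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a measurement table as CSV
#'
#' Writes a header + one line per record, UTF-8, '.' decimal separator, in
#' the column order of the input. Numeric columns are serialised with 17
#' significant digits so that [readMeasurementTable()] reproduces the values
#' bit-exactly.
#'
#' @param rows a data.frame (possibly 0-row) of homogeneous records.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurementTable <- function(rows, path) {
    rows <- as.data.frame(rows)
    out <- rows
    for (j in seq_along(out))
        if (is.double(out[[j]]))
            out[[j]] <- sprintf("%.17g", out[[j]])
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeMeasurementTable
#' @export
readMeasurementTable <- function(path) {
    if (!file.exists(path))
        stop("table not found: ", path)
    utils::read.csv(path, encoding = "UTF-8")
}
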