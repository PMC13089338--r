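#' Accessors for calibrated grids and shapes
#'
#' \code{pixels} returns the raw intensity (or mask) matrix, \code{pixelSize}
#' the isotropic calibration in micrometres per pixel, \code{channelName} the
#' channel label, and \code{arcLength} the total polyline length in
#' micrometres.
#'
#' @param x a mesoquant object.
#' @return \code{pixels}: a matrix; \code{pixelSize}, \code{arcLength}:
#'   a single numeric; \code{channelName}: a string.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname accessors
setMethod("pixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
setMethod("pixels", "MaskImage", function(x) x@pixels)

#' @rdname accessors
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "MaskImage", function(x) x@pixelSize)

#' @rdname accessors
setMethod("channelName", "CalibratedImage", function(x) x@channelName)

#' @rdname accessors
setMethod("arcLength", "PolylineROI", function(x) {
    p <- x@points
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
})

setMethod("show", "CalibratedImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("CalibratedImage '%s': %d x %d px @ %.4g um/px (%.4g x %.4g um)\n",
                object@channelName, d[1], d[2], object@pixelSize,
                d[1] * object@pixelSize, d[2] * object@pixelSize))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "MaskImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("MaskImage: %d x %d px @ %.4g um/px, %d foreground px (%.3g um^2)\n",
                d[1], d[2], object@pixelSize, sum(object@pixels),
                sum(object@pixels) * object@pixelSize^2))
})

setMethod("show", "PolylineROI", function(object) {
    cat(sprintf("PolylineROI: %d points, arc length %.4g um\n",
                nrow(object@points), arcLength(object)))
})

setMethod("show", "StraightenedMap", function(object) {
    cat(sprintf("StraightenedMap: %d axial x %d transverse samples, half-width %.3g um, arc %.4g um\n",
                length(object@s), length(object@d), object@halfWidth,
                object@arcLength))
    cat(sprintf("  missing samples: %d of %d\n",
                sum(is.na(object@grid)), length(object@grid)))
})

setMethod("show", "BodyShape", function(object) {
    cat(sprintf("BodyShape: l = %.4g um, w = %.4g um, AR = %.4g, angle = %.3g deg",
                object@l, object@w, object@AR, object@axisAngle))
    if (!is.na(object@volume))
        cat(sprintf(", volume = %.4g um^3", object@volume))
    cat("\n")
})

setMethod("show", "PatchShape", function(object) {
    cat(sprintf("PatchShape: A = %.4g um^2, l = %.4g um, w = %.4g um, ARpatch = %.4g%s%s\n",
                object@A, object@l, object@w, object@ARpatch,
                if (object@inverted) " (inverted)" else "",
                if (object@degenerate) " (degenerate skeleton)" else ""))
})

setMethod("show", "AboralProfile", function(object) {
    cat(sprintf("AboralProfile '%s': %d samples over [%.3g, %.3g] um (0 = pore), line width %.3g um\n",
                object@channel, length(object@positions),
                min(object@positions), max(object@positions),
                object@lineWidth))
})

setMethod("show", "ProfileEnsemble", function(object) {
    cat(sprintf("ProfileEnsemble '%s': n = %d profiles on %d shared positions\n",
                object@channel, nrow(object@profiles),
                length(object@positions)))
})

setMethod("show", "MorphospaceTrajectory", function(object) {
    cat(sprintf("MorphospaceTrajectory: %d frames over %.4g min, %d leakage event(s)\n",
                nrow(object@frames), diff(range(object@frames$t)),
                nrow(object@events)))
})

#' Frames and events of a morphospace trajectory
#'
#' @param x a [MorphospaceTrajectory-class].
#' @return \code{trajectoryFrames}: the per-frame data.frame;
#'   \code{trajectoryEvents}: the detected leakage-event data.frame.
#' @export
trajectoryFrames <- function(x) {
    stopifnot(is(x, "MorphospaceTrajectory"))
    x@frames
}

#' @rdname trajectoryFrames
#' @export
trajectoryEvents <- function(x) {
    stopifnot(is(x, "MorphospaceTrajectory"))
    x@events
}
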