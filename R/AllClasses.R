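#' @import methods
NULL

#' Calibrated fluorescence image
#'
#' A 2D intensity grid with an isotropic physical calibration. This is the
#' universal input of the package: every downstream operation works in
#' micrometres, never in pixels. Pixel centres sit at integer indices, so the
#' physical coordinate of pixel \code{[r, c]} is
#' \code{x = (c - 1) * pixelSize}, \code{y = (r - 1) * pixelSize}
#' (0-based physical origin at the first pixel centre, y increasing with row).
#'
#' @slot pixels numeric matrix of non-negative, finite intensities
#'   (arbitrary units).
#' @slot pixelSize single positive numeric, micrometres per pixel (isotropic).
#' @slot channelName free-text channel label, e.g. \code{"ColIV"},
#'   \code{"Laminin"}, \code{"pErk"}.
#'
#' @seealso [CalibratedImage()] for the constructor,
#'   [readCalibratedImage()] for the TIFF reader.
#' @exportClass CalibratedImage
setClass("CalibratedImage",
    representation(
        pixels = "matrix",
        pixelSize = "numeric",
        channelName = "character"
    ),
    prototype(pixelSize = 1, channelName = "")
)

setValidity("CalibratedImage", function(object) {
    msg <- character()
    px <- object@pixels
    if (!is.numeric(px))
        msg <- c(msg, "'pixels' must be a numeric matrix")
    if (nrow(px) < 2L || ncol(px) < 2L)
        msg <- c(msg, "'pixels' must have at least 2 rows and 2 columns")
    if (is.numeric(px) && !all(is.finite(px)))
        msg <- c(msg, "intensities must be finite")
    if (is.numeric(px) && any(px < 0))
        msg <- c(msg, "intensities must be non-negative")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number (um/px)")
    if (length(object@channelName) != 1L)
        msg <- c(msg, "'channelName' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixelSize micrometres per pixel (isotropic, > 0).
#' @param channelName channel label.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(matrix(runif(100), 10, 10), pixelSize = 0.5)
#' pixelSize(img)
#' @export
CalibratedImage <- function(pixels, pixelSize, channelName = "") {
    new("CalibratedImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
        channelName = as.character(channelName))
}

#' Binary mask with physical calibration
#'
#' Same grid contract as [CalibratedImage-class] but holding a 0/1
#' segmentation mask (e.g. a segmented body column or photoconverted patch).
#'
#' @slot pixels numeric matrix containing only 0 and 1.
#' @slot pixelSize micrometres per pixel.
#' @exportClass MaskImage
setClass("MaskImage",
    representation(pixels = "matrix", pixelSize = "numeric"),
    prototype(pixelSize = 1)
)

setValidity("MaskImage", function(object) {
    msg <- character()
    px <- object@pixels
    if (!is.numeric(px))
        msg <- c(msg, "'pixels' must be a numeric 0/1 matrix")
    if (nrow(px) < 2L || ncol(px) < 2L)
        msg <- c(msg, "'pixels' must have at least 2 rows and 2 columns")
    if (is.numeric(px) && !all(px %in% c(0, 1)))
        msg <- c(msg, "mask values must be 0 or 1")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number (um/px)")
    if (length(msg)) msg else TRUE
})

#' Construct a MaskImage
#'
#' @param pixels matrix of 0/1 (logical matrices are coerced).
#' @param pixelSize micrometres per pixel.
#' @return A [MaskImage-class] object.
#' @export
MaskImage <- function(pixels, pixelSize) {
    storage.mode(pixels) <- "double"
    new("MaskImage", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Open polyline region of interest
#'
#' An ordered list of (x, y) vertices in micrometres, used to trace the
#' mesoglea midline or the oral-aboral axis. Always open (never closed).
#'
#' @slot points n x 2 numeric matrix, columns x and y in micrometres.
#' @slot closed logical; always \code{FALSE} in this package.
#' @exportClass PolylineROI
setClass("PolylineROI",
    representation(points = "matrix", closed = "logical"),
    prototype(closed = FALSE)
)

setValidity("PolylineROI", function(object) {
    p <- object@points
    msg <- character()
    if (!is.numeric(p) || ncol(p) != 2L)
        msg <- c(msg, "'points' must be an n x 2 numeric matrix (x, y) in um")
    if (nrow(p) < 2L)
        msg <- c(msg, "a polyline needs at least 2 points")
    if (is.numeric(p) && !all(is.finite(p)))
        msg <- c(msg, "polyline coordinates must be finite")
    if (is.numeric(p) && nrow(p) >= 2L) {
        seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2))
        if (any(seg == 0))
            msg <- c(msg, "consecutive polyline points must be distinct")
        if (sum(seg) <= 0)
            msg <- c(msg, "polyline must have positive arc length")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PolylineROI
#'
#' @param points n x 2 matrix or data.frame of (x, y) in micrometres.
#' @return A [PolylineROI-class] object.
#' @examples
#' roi <- PolylineROI(cbind(x = c(0, 10), y = c(0, 0)))
#' arcLength(roi)
#' @export
PolylineROI <- function(points) {
    points <- as.matrix(points)
    colnames(points) <- c("x", "y")
    new("PolylineROI", points = points, closed = FALSE)
}

#' Straightened tissue map
#'
#' The image resampled into mesoglea-centred coordinates: axial position
#' \code{s} (normalised arc length along the polyline, in [0, 1]) against
#' signed transverse offset \code{d} in micrometres. \code{d = 0} is the
#' polyline; positive \code{d} is to the left of the direction of travel,
#' which by convention is the endoderm side (the caller orients the polyline
#' accordingly). Samples falling outside the image are \code{NA}.
#'
#' @slot grid numeric matrix, rows indexed by \code{d}, columns by \code{s}.
#' @slot s numeric vector of normalised axial positions (strictly increasing).
#' @slot d numeric vector of transverse offsets in micrometres, symmetric
#'   about 0.
#' @slot halfWidth transverse half extent in micrometres.
#' @slot arcLength total polyline arc length in micrometres.
#' @exportClass StraightenedMap
setClass("StraightenedMap",
    representation(
        grid = "matrix",
        s = "numeric",
        d = "numeric",
        halfWidth = "numeric",
        arcLength = "numeric"
    )
)

setValidity("StraightenedMap", function(object) {
    msg <- character()
    if (nrow(object@grid) != length(object@d))
        msg <- c(msg, "grid rows must match length(d)")
    if (ncol(object@grid) != length(object@s))
        msg <- c(msg, "grid columns must match length(s)")
    if (any(diff(object@s) <= 0))
        msg <- c(msg, "'s' must be strictly increasing")
    if (max(abs(object@d + rev(object@d))) > 1e-9)
        msg <- c(msg, "'d' sampling must be symmetric about 0")
    if (length(msg)) msg else TRUE
})

#' Pore-centred aboral intensity profile
#'
#' Intensity sampled along a line across the aboral pole, averaged over a
#' perpendicular width, with positions expressed in micrometres relative to
#' the pore (0 = pore).
#'
#' @slot positions numeric vector, micrometres relative to the pore.
#' @slot intensity numeric vector, same length as positions.
#' @slot channel channel label.
#' @slot roiLength length of the profiled window in micrometres.
#' @slot lineWidth perpendicular averaging width in micrometres.
#' @exportClass AboralProfile
setClass("AboralProfile",
    representation(
        positions = "numeric",
        intensity = "numeric",
        channel = "character",
        roiLength = "numeric",
        lineWidth = "numeric"
    )
)

setValidity("AboralProfile", function(object) {
    msg <- character()
    if (length(object@positions) != length(object@intensity))
        msg <- c(msg, "positions and intensity must have equal length")
    if (any(diff(object@positions) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
    span <- diff(range(object@positions))
    if (span > object@roiLength + 1e-6)
        msg <- c(msg, "positions span exceeds roiLength")
    if (length(msg)) msg else TRUE
})

#' Aligned multi-animal profile ensemble
#'
#' Profiles from several animals resampled onto a shared position grid, with
#' the per-position mean and standard deviation used for mean +/- SD band
#' plots.
#'
#' @slot positions shared position grid (micrometres relative to pore).
#' @slot profiles n x length(positions) matrix, one row per animal.
#' @slot mean per-position mean.
#' @slot sd per-position standard deviation (denominator n - 1; 0 when n = 1).
#' @slot channel channel label.
#' @exportClass ProfileEnsemble
setClass("ProfileEnsemble",
    representation(
        positions = "numeric",
        profiles = "matrix",
        mean = "numeric",
        sd = "numeric",
        channel = "character"
    )
)

setValidity("ProfileEnsemble", function(object) {
    msg <- character()
    if (ncol(object@profiles) != length(object@positions))
        msg <- c(msg, "profile columns must match the position grid")
    if (nrow(object@profiles) < 1L)
        msg <- c(msg, "ensemble needs at least one profile")
    if (length(msg)) msg else TRUE
})

#' Body-column shape metrics
#'
#' Length, width, aspect ratio and solid-of-revolution volume of a segmented
#' body column, oriented along the moment principal axis (the oral-aboral
#' direction). The orientation tie-break guarantees \code{l >= w}, hence
#' \code{AR >= 1}.
#'
#' @slot l length in micrometres, parallel to the oral-aboral axis.
#' @slot w width in micrometres, perpendicular to that axis.
#' @slot AR dimensionless aspect ratio l / w.
#' @slot volume solid-of-revolution volume in cubic micrometres
#'   (\code{NA} until [estimateVolume()] is applied).
#' @slot axisAngle principal-axis angle in degrees (image x axis = 0,
#'   measured towards +y).
#' @exportClass BodyShape
setClass("BodyShape",
    representation(l = "numeric", w = "numeric", AR = "numeric",
                   volume = "numeric", axisAngle = "numeric")
)

setValidity("BodyShape", function(object) {
    msg <- character()
    if (object@w <= 0 || object@l < object@w)
        msg <- c(msg, "requires l >= w > 0")
    if (abs(object@AR - object@l / object@w) > 1e-9)
        msg <- c(msg, "AR must equal l / w")
    if (!is.na(object@volume) && object@volume <= 0)
        msg <- c(msg, "volume must be positive when set")
    if (length(msg)) msg else TRUE
})

#' Photoconverted-patch shape metrics
#'
#' Elongation scoring of a photoconverted tissue patch: area \code{A},
#' skeleton length \code{l}, empirical width \code{w = A / l} and the
#' elongation index \code{ARpatch = l^2 / A} (equivalently l / w).
#'
#' @slot A patch area in square micrometres.
#' @slot l skeleton (longest geodesic path) length in micrometres.
#' @slot w empirical width A / l in micrometres.
#' @slot ARpatch dimensionless elongation index l^2 / A.
#' @slot inverted logical; \code{TRUE} after [applyInversion()] with
#'   \code{invert = TRUE} (reciprocal AR).
#' @slot degenerate logical; \code{TRUE} when the skeleton collapsed towards
#'   a point (near-circular patch), making l unreliable.
#' @exportClass PatchShape
setClass("PatchShape",
    representation(A = "numeric", l = "numeric", w = "numeric",
                   ARpatch = "numeric", inverted = "logical",
                   degenerate = "logical"),
    prototype(inverted = FALSE, degenerate = FALSE)
)

setValidity("PatchShape", function(object) {
    msg <- character()
    if (object@A <= 0)
        msg <- c(msg, "area must be positive")
    if (!object@degenerate && object@l <= 0)
        msg <- c(msg, "skeleton length must be positive for non-degenerate patches")
    if (length(msg)) msg else TRUE
})

#' Morphospace trajectory with leakage events
#'
#' A per-frame record of time, body volume and aspect ratio, plus the abrupt
#' volume-drop (aboral leakage) events detected on the smoothed volume trace.
#'
#' @slot frames data.frame with columns \code{frame}, \code{t} (minutes),
#'   \code{volume} (um^3, raw), \code{AR} and \code{volumeSmooth} (the
#'   rolling-median trace used for event detection).
#' @slot events data.frame with columns \code{frame}, \code{kind},
#'   \code{dropFraction}, \code{ARAtOnset} (empty until
#'   [detectLeakageOnset()] runs).
#' @exportClass MorphospaceTrajectory
setClass("MorphospaceTrajectory",
    representation(frames = "data.frame", events = "data.frame")
)

setValidity("MorphospaceTrajectory", function(object) {
    msg <- character()
    fr <- object@frames
    need <- c("frame", "t", "volume", "AR", "volumeSmooth")
    if (!all(need %in% names(fr)))
        msg <- c(msg, paste("frames must have columns",
                            paste(need, collapse = ", ")))
    else if (any(diff(fr$t) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    ev <- object@events
    if (nrow(ev) && (any(ev$dropFraction <= 0) || any(ev$dropFraction >= 1)))
        msg <- c(msg, "event drop fractions must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})
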