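#' Pore-centred intensity profile at the aboral end
#'
#' Samples intensity along a line across the aboral pore, averaging over
#' \code{lineWidth} perpendicular to the line at each position, and shifts
#' the position axis so the pore sits at 0. The profiled window has length
#' \code{roiLength} (default 100 um) centred on the pore where the line
#' allows, otherwise shifted to fit within the line.
#'
#' @param image a [CalibratedImage-class].
#' @param line a [PolylineROI-class] of arc length >= \code{roiLength}.
#' @param porePosition position of the pore in micrometres of arc length
#'   along the line.
#' @param roiLength profiled window length, micrometres.
#' @param lineWidth perpendicular averaging width, micrometres (0 = single
#'   line sample).
#' @param step sampling step, micrometres (default: pixel size).
#' @param normalize if \code{TRUE}, positions are additionally rescaled to
#'   [-0.5, 0.5] by the ROI length instead of micrometres.
#' @return An [AboralProfile-class].
#' @export
extractAboralProfile <- function(image, line, porePosition,
                                 roiLength = 100, lineWidth = 5,
                                 step = pixelSize(image),
                                 normalize = FALSE) {
    stopifnot(is(image, "CalibratedImage"), is(line, "PolylineROI"))
    total <- arcLength(line)
    if (total < roiLength - 1e-9)
        stop("line shorter than the requested ROI length")
    if (porePosition < 0 || porePosition > total)
        stop("pore position outside the line")
    start <- min(max(porePosition - roiLength / 2, 0), total - roiLength)
    at <- seq(start, start + roiLength,
              length.out = max(2L, floor(roiLength / step) + 1L))
    par <- polylinePointsAt(line@points, at)
    if (!polylineInsideImage(line@points, image@pixels, image@pixelSize))
        stop("line exits the image")
    if (lineWidth > 0) {
        nx <- -par$tangents[, 2L]
        ny <- par$tangents[, 1L]
        nHalf <- max(1L, ceiling(lineWidth / 2 / step))
        off <- seq(-nHalf, nHalf) / nHalf * lineWidth / 2
        xp <- matrix(par$points[, 1L], length(off), length(at),
                     byrow = TRUE) + outer(off, nx, `*`)
        yp <- matrix(par$points[, 2L], length(off), length(at),
                     byrow = TRUE) + outer(off, ny, `*`)
        vals <- sampleBilinear(image@pixels, image@pixelSize,
                               as.vector(xp), as.vector(yp))
        intensity <- colMeans(matrix(vals, nrow = length(off)),
                              na.rm = TRUE)
    } else {
        intensity <- sampleBilinear(image@pixels, image@pixelSize,
                                    par$points[, 1L], par$points[, 2L])
    }
    pos <- at - porePosition
    if (normalize) pos <- pos / roiLength
    new("AboralProfile", positions = pos, intensity = intensity,
        channel = channelName(image),
        roiLength = if (normalize) 1 else roiLength,
        lineWidth = lineWidth)
}

#' pErk line profile at the aboral pore
#'
#' Specialisation of [extractAboralProfile()] for the wound-response
#' readout: a 0-50 um profile across a line of width 5 um, with position 0
#' at the outside end of the line (the line is drawn from outside the
#' animal inward into the body cavity).
#'
#' @param image a [CalibratedImage-class] of the pErk channel.
#' @param line a [PolylineROI-class] of arc length >= \code{span}, drawn
#'   outside-in.
#' @param span profiled length from the outside end, micrometres.
#' @param lineWidth perpendicular averaging width, micrometres.
#' @param step sampling step, micrometres.
#' @return An [AboralProfile-class] with positions in [0, span].
#' @export
perkProfile <- function(image, line, span = 50, lineWidth = 5,
                        step = pixelSize(image)) {
    stopifnot(is(image, "CalibratedImage"), is(line, "PolylineROI"))
    if (arcLength(line) < span - 1e-9)
        stop("line shorter than the requested span")
    prof <- extractAboralProfile(image, line, porePosition = 0,
                                 roiLength = span, lineWidth = lineWidth,
                                 step = step)
    # positions from extractAboralProfile are relative to pore = 0 at the
    # outside end already; keep the [0, span] convention
    initialize(prof, positions = prof@positions - min(prof@positions))
}

#' Width and depth of the aboral Col IV depletion zone
#'
#' The flank level is the mean of the outer 20 percent of samples on each
#' side of the profile; the depth is \code{1 - min / flank}; the width is
#' the distance between the two linearly interpolated crossings of the
#' half-depth level \code{(flank + min) / 2} nearest the minimum (full
#' width at half depth, mirroring the FWHM thickness convention). The width
#' is invariant to intensity gain and offset; the depth to gain.
#'
#' @param profile an [AboralProfile-class] with flanking plateaus on both
#'   sides of the dip.
#' @param noiseFloor smallest depth treated as a real dip; shallower
#'   profiles raise a no-dip error.
#' @param edgeFraction fraction of samples per side used for the flank
#'   level.
#' @return List with \code{width} (um), \code{depth} (fraction),
#'   \code{center} (um) and \code{flank} (intensity).
#' @export
depletionZoneWidth <- function(profile, noiseFloor = 0.05,
                               edgeFraction = 0.2) {
    stopifnot(is(profile, "AboralProfile"))
    pos <- profile@positions
    y <- profile@intensity
    keep <- is.finite(y)
    pos <- pos[keep]; y <- y[keep]
    n <- length(y)
    if (n < 5L) stop("profile too short")
    k <- max(1L, floor(edgeFraction * n))
    flank <- mean(c(y[seq_len(k)], y[seq.int(n - k + 1L, n)]))
    if (flank <= 0) stop("non-positive flank level")
    imin <- which.min(y)
    depth <- 1 - y[imin] / flank
    if (depth <= noiseFloor)
        stop("no dip: profile depth ", signif(depth, 3),
             " below the noise floor")
    if (imin == 1L || imin == n)
        stop("missing flank: minimum at the profile boundary")
    level <- (flank + y[imin]) / 2
    left <- .crossingUp(pos, y, imin, level, dir = -1L)
    right <- .crossingUp(pos, y, imin, level, dir = +1L)
    if (is.na(left) || is.na(right))
        stop("missing flank: half-depth crossing not bracketed")
    list(width = right - left, depth = depth,
         center = (left + right) / 2, flank = flank)
}

# linear-interpolated crossing where y rises back above `level`, walking
# away from the minimum
.crossingUp <- function(pos, y, imin, level, dir) {
    i <- imin
    repeat {
        j <- i + dir
        if (j < 1L || j > length(y)) return(NA_real_)
        if (y[j] >= level) {
            frac <- (level - y[i]) / (y[j] - y[i])
            return(pos[i] + frac * (pos[j] - pos[i]))
        }
        i <- j
    }
}

#' Align profiles from several animals into a mean +/- SD ensemble
#'
#' Resamples all profiles onto a shared position grid (the overlap of their
#' position ranges, at the resolution of the first profile) by linear
#' interpolation, then computes the per-position mean and standard deviation
#' (denominator n - 1; SD = 0 when n = 1), as used for mean +/- SD band
#' plots across animals.
#'
#' @param profiles list of [AboralProfile-class] sharing one channel.
#' @return A [ProfileEnsemble-class].
#' @importFrom stats approx sd
#' @export
ensembleProfiles <- function(profiles) {
    if (!length(profiles)) stop("need at least one profile")
    chans <- unique(vapply(profiles, function(p) p@channel, character(1)))
    if (length(chans) != 1L)
        stop("channel mismatch across profiles: ",
             paste(chans, collapse = ", "))
    lo <- max(vapply(profiles, function(p) min(p@positions), numeric(1)))
    hi <- min(vapply(profiles, function(p) max(p@positions), numeric(1)))
    if (lo >= hi) stop("profiles have non-overlapping position ranges")
    ref <- profiles[[1L]]@positions
    grid <- ref[ref >= lo & ref <= hi]
    if (length(grid) < 2L)
        grid <- seq(lo, hi, length.out = 50L)
    mat <- t(vapply(profiles, function(p)
        stats::approx(p@positions, p@intensity, xout = grid)$y,
        numeric(length(grid))))
    sds <- if (nrow(mat) == 1L) rep(0, ncol(mat))
           else apply(mat, 2L, stats::sd)
    new("ProfileEnsemble", positions = grid, profiles = mat,
        mean = colMeans(mat), sd = sds, channel = chans)
}

#' Mean intensity over equal-sized square ROIs
#'
#' Average intensity per square ROI (all sharing one side length), as used
#' for ECM intensity readouts on maximum-intensity projections. The
#' projection itself is the caller's input; this function does not project.
#' A pixel belongs to a ROI when its centre falls inside the square.
#'
#' @param image a [CalibratedImage-class].
#' @param roiCenters n x 2 matrix or data.frame of square centres (x, y) in
#'   micrometres.
#' @param roiSide side length of the squares in micrometres; every square
#'   must lie fully inside the image.
#' @return Numeric vector of per-ROI mean intensities.
#' @export
roiMeanIntensity <- function(image, roiCenters, roiSide) {
    stopifnot(is(image, "CalibratedImage"))
    if (length(roiSide) != 1L || roiSide <= 0)
        stop("'roiSide' must be a single positive length (all ROIs equal)")
    ctr <- as.matrix(roiCenters)
    ps <- image@pixelSize
    xmax <- (ncol(image@pixels) - 1) * ps
    ymax <- (nrow(image@pixels) - 1) * ps
    xs <- (seq_len(ncol(image@pixels)) - 1) * ps
    ys <- (seq_len(nrow(image@pixels)) - 1) * ps
    apply(ctr, 1L, function(cc) {
        x0 <- cc[1L] - roiSide / 2; x1 <- cc[1L] + roiSide / 2
        y0 <- cc[2L] - roiSide / 2; y1 <- cc[2L] + roiSide / 2
        if (x0 < -ps / 2 || y0 < -ps / 2 ||
            x1 > xmax + ps / 2 || y1 > ymax + ps / 2)
            stop("ROI exceeds image bounds")
        cols <- which(xs >= x0 & xs <= x1)
        rows <- which(ys >= y0 & ys <= y1)
        if (!length(cols) || !length(rows))
            stop("ROI contains no pixel centres")
        mean(image@pixels[rows, cols])
    })
}
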