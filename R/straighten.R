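#' Straighten an image along a polyline ROI
#'
#' Resamples the image by bilinear interpolation at points
#' \code{p(s) + d * n(s)}, where \code{p(s)} is the arc-length-parameterised
#' polyline and \code{n(s)} the unit normal (left of the direction of
#' travel = positive \code{d}; orient the polyline so the endoderm lies on
#' the positive side). This turns a curved mesoglea into a horizontal band:
#' axial position \code{s} is rescaled to [0, 1], transverse offset \code{d}
#' is in micrometres with the polyline at 0. Samples falling outside the
#' image are recorded as \code{NA} (missing), never zero-filled.
#'
#' @param image a [CalibratedImage-class].
#' @param roi a [PolylineROI-class]; every vertex must lie inside the image.
#' @param halfWidth transverse half extent in micrometres (> 0).
#' @param axialStep,transverseStep sampling steps in micrometres
#'   (default: the pixel size).
#' @return A [StraightenedMap-class].
#' @export
straighten <- function(image, roi, halfWidth,
                       axialStep = pixelSize(image),
                       transverseStep = pixelSize(image)) {
    stopifnot(is(image, "CalibratedImage"), is(roi, "PolylineROI"))
    if (halfWidth <= 0) stop("'halfWidth' must be positive")
    if (!polylineInsideImage(roi@points, image@pixels, image@pixelSize))
        stop("polyline exits the image")
    total <- arcLength(roi)
    nS <- max(2L, floor(total / axialStep) + 1L)
    at <- seq(0, total, length.out = nS)
    par <- polylinePointsAt(roi@points, at)
    nHalf <- ceiling(halfWidth / transverseStep)
    d <- seq(-nHalf, nHalf) * transverseStep
    # normals: left of travel
    nx <- -par$tangents[, 2L]
    ny <- par$tangents[, 1L]
    xp <- matrix(par$points[, 1L], length(d), nS, byrow = TRUE) +
          outer(d, nx, `*`)
    yp <- matrix(par$points[, 2L], length(d), nS, byrow = TRUE) +
          outer(d, ny, `*`)
    vals <- sampleBilinear(image@pixels, image@pixelSize,
                           as.vector(xp), as.vector(yp))
    grid <- matrix(vals, nrow = length(d), ncol = nS)
    new("StraightenedMap", grid = grid, s = at / total, d = d,
        halfWidth = halfWidth, arcLength = total)
}

#' Average transverse intensity profile of a straightened map
#'
#' Averages the map over axial positions within \code{sRange}, ignoring
#' missing samples, giving mean intensity as a function of the signed
#' transverse offset \code{d}.
#'
#' @param map a [StraightenedMap-class].
#' @param sRange numeric length-2 interval of normalised axial positions, or
#'   \code{NULL} for the full column.
#' @return data.frame with columns \code{d} (um) and \code{intensity}.
#' @export
transverseProfile <- function(map, sRange = NULL) {
    stopifnot(is(map, "StraightenedMap"))
    cols <- if (is.null(sRange)) seq_along(map@s)
            else which(map@s >= sRange[1L] & map@s <= sRange[2L])
    if (!length(cols)) stop("empty s range")
    data.frame(d = map@d,
               intensity = rowMeans(map@grid[, cols, drop = FALSE],
                                    na.rm = TRUE))
}

#' Full width at half maximum of an intensity peak
#'
#' The local mesoglea thickness estimator. The baseline is the mean of the
#' outer 10 percent of samples on each side (robust to tissue shoulders);
#' the peak is the maximum after baseline subtraction; the half-maximum
#' crossings nearest the peak on each flank are located by linear
#' interpolation; the width is their distance. By this construction the
#' estimate is exactly invariant to affine intensity transforms
#' (gain and offset).
#'
#' @param d positions in micrometres (strictly increasing), or a data.frame
#'   with columns \code{d} and \code{intensity} (as from
#'   [transverseProfile()]).
#' @param intensity intensities at \code{d} (ignored when \code{d} is a
#'   data.frame).
#' @param edgeFraction fraction of samples on each side used for the
#'   baseline.
#' @param minSNR minimum ratio of the baseline-subtracted peak to the
#'   standard deviation of the edge samples: profiles whose apparent peak
#'   is indistinguishable from baseline fluctuation (e.g. pure noise) are
#'   rejected rather than yielding a spurious width.
#' @return List with \code{width} (um), \code{center} (um),
#'   \code{halfLevel} (intensity), \code{peak} (baseline-subtracted height)
#'   and \code{baseline}.
#' @export
fwhm <- function(d, intensity = NULL, edgeFraction = 0.1, minSNR = 5) {
    if (is.data.frame(d)) {
        intensity <- d$intensity
        d <- d$d
    }
    keep <- is.finite(intensity)
    d <- d[keep]; intensity <- intensity[keep]
    n <- length(d)
    if (n < 5L) stop("profile too short for FWHM estimation")
    k <- max(1L, floor(edgeFraction * n))
    baseline <- mean(c(intensity[seq_len(k)],
                       intensity[seq.int(n - k + 1L, n)]))
    y <- intensity - baseline
    imax <- which.max(y)
    pk <- y[imax]
    if (pk <= 0) stop("no peak above the edge baseline")
    edgeSD <- stats::sd(c(intensity[seq_len(k)],
                          intensity[seq.int(n - k + 1L, n)]))
    if (is.finite(edgeSD) && edgeSD > 0 && pk <= minSNR * edgeSD)
        stop("no significant peak above the edge baseline ",
             "(peak/edge-noise ratio ", signif(pk / edgeSD, 3), ")")
    if (imax == 1L || imax == n)
        stop("peak at the profile boundary: flank not bracketed")
    half <- pk / 2
    left <- .crossing(d, y, imax, half, dir = -1L)
    right <- .crossing(d, y, imax, half, dir = +1L)
    if (is.na(left) || is.na(right))
        stop("half-maximum flank not bracketed within the profile")
    list(width = right - left, center = (left + right) / 2,
         halfLevel = baseline + half, peak = pk, baseline = baseline)
}

# linear-interpolated half crossing nearest the peak, walking from imax
.crossing <- function(d, y, imax, level, dir) {
    i <- imax
    repeat {
        j <- i + dir
        if (j < 1L || j > length(y)) return(NA_real_)
        if (y[j] <= level) {
            frac <- (y[i] - level) / (y[i] - y[j])
            return(d[i] + frac * (d[j] - d[i]))
        }
        i <- j
    }
}

#' Mesoglea thickness and amount along the body column
#'
#' Applies [fwhm()] per axial bin (default 5 axial samples per bin, to
#' stabilise noisy flank crossings) of a straightened map. The local Col IV
#' \emph{amount} is reported both as the sum and as the mean of
#' baseline-subtracted intensity within the local FWHM window. Axial
#' positions where no peak is found are excluded and counted.
#'
#' @param map a [StraightenedMap-class].
#' @param bin number of axial samples per bin (>= 1).
#' @param edgeFraction passed to [fwhm()].
#' @return List with \code{perS} (data.frame: s, thickness, amountSum,
#'   amountMean, center), \code{summary} (meanThickness, sdThickness,
#'   meanAmountSum, sdAmountSum, meanAmountMean, sdAmountMean) and
#'   \code{nUndefined}.
#' @importFrom stats sd
#' @export
thicknessAlongColumn <- function(map, bin = 5L, edgeFraction = 0.1) {
    stopifnot(is(map, "StraightenedMap"))
    bin <- max(1L, as.integer(bin))
    nS <- length(map@s)
    starts <- seq.int(1L, nS, by = bin)
    rows <- vector("list", length(starts))
    nUndef <- 0L
    for (i in seq_along(starts)) {
        cols <- starts[i]:min(starts[i] + bin - 1L, nS)
        prof <- rowMeans(map@grid[, cols, drop = FALSE], na.rm = TRUE)
        res <- tryCatch(fwhm(map@d, prof, edgeFraction = edgeFraction),
                        error = function(e) NULL)
        if (is.null(res)) {
            nUndef <- nUndef + 1L
            next
        }
        inWin <- map@d >= res$center - res$width / 2 &
                 map@d <= res$center + res$width / 2
        sub <- prof[inWin] - res$baseline
        rows[[i]] <- data.frame(
            s = mean(map@s[cols]), thickness = res$width,
            amountSum = sum(sub, na.rm = TRUE),
            amountMean = mean(sub, na.rm = TRUE),
            center = res$center)
    }
    perS <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(perS) || nrow(perS) == 0L)
        stop("no axial position yields a defined mesoglea peak")
    list(perS = perS,
         summary = list(
             meanThickness = mean(perS$thickness),
             sdThickness = stats::sd(perS$thickness),
             meanAmountSum = mean(perS$amountSum),
             sdAmountSum = stats::sd(perS$amountSum),
             meanAmountMean = mean(perS$amountMean),
             sdAmountMean = stats::sd(perS$amountMean)),
         nUndefined = nUndef)
}

#' Extracellular-to-intracellular intensity ratio
#'
#' Ratio of the mean baseline-subtracted intensity within the mesoglea FWHM
#' window to the mean intensity within an endoderm band on the positive-d
#' side, as a gain-invariant readout of extracellular versus intracellular
#' signal.
#'
#' @param map a [StraightenedMap-class], positive d = endoderm side.
#' @param endodermBand length-2 numeric, the (d_lo, d_hi) band in
#'   micrometres; must lie on the positive side and be disjoint from the
#'   mesoglea window.
#' @param mesogleaWindow optional length-2 numeric (d_lo, d_hi) of the
#'   mesoglea window; computed from [fwhm()] of the full-column transverse
#'   profile when \code{NULL}.
#' @param edgeFraction passed to [fwhm()].
#' @return List with \code{ratio}, \code{mesogleaWindow},
#'   \code{mesogleaMean} and \code{endodermMean}.
#' @export
ecIcRatio <- function(map, endodermBand, mesogleaWindow = NULL,
                      edgeFraction = 0.1) {
    stopifnot(is(map, "StraightenedMap"), length(endodermBand) == 2L)
    if (endodermBand[1L] >= endodermBand[2L])
        stop("'endodermBand' must be (d_lo, d_hi) with d_lo < d_hi")
    if (endodermBand[1L] < 0)
        stop("'endodermBand' must lie on the positive-d (endoderm) side")
    prof <- transverseProfile(map)
    pk <- fwhm(prof, edgeFraction = edgeFraction)
    if (is.null(mesogleaWindow))
        mesogleaWindow <- c(pk$center - pk$width / 2,
                            pk$center + pk$width / 2)
    if (endodermBand[1L] < mesogleaWindow[2L])
        stop("endoderm band overlaps the mesoglea window")
    inMeso <- prof$d >= mesogleaWindow[1L] & prof$d <= mesogleaWindow[2L]
    inEndo <- prof$d >= endodermBand[1L] & prof$d <= endodermBand[2L]
    if (!any(inEndo)) stop("endoderm band contains no samples")
    mesoMean <- mean(prof$intensity[inMeso] - pk$baseline, na.rm = TRUE)
    endoMean <- mean(prof$intensity[inEndo], na.rm = TRUE)
    if (!is.finite(endoMean) || endoMean <= 0)
        stop("non-positive endoderm-band denominator")
    list(ratio = mesoMean / endoMean, mesogleaWindow = mesogleaWindow,
         mesogleaMean = mesoMean, endodermMean = endoMean)
}

#' Intensity profile along the oral-aboral axis
#'
#' Samples the image along an axis polyline (optionally averaging over a
#' perpendicular width) and rescales position to [0, 1]. By convention the
#' polyline is drawn from the aboral towards the oral pole; with
#' \code{origin = "aboral"} (default) position 0 is the polyline start
#' (aboral), with \code{origin = "oral"} the axis is flipped so 0 is the
#' oral pole.
#'
#' @param image a [CalibratedImage-class].
#' @param axisRoi a [PolylineROI-class] along the oral-aboral axis (drawn
#'   aboral to oral).
#' @param width perpendicular averaging width in micrometres (0 = single
#'   line).
#' @param step sampling step in micrometres (default: pixel size).
#' @param origin which pole is position 0, \code{"aboral"} or \code{"oral"}.
#' @return data.frame with columns \code{position} (in [0, 1]) and
#'   \code{intensity}.
#' @export
axialIntensityProfile <- function(image, axisRoi, width = 0,
                                  step = pixelSize(image),
                                  origin = c("aboral", "oral")) {
    origin <- match.arg(origin)
    stopifnot(is(image, "CalibratedImage"), is(axisRoi, "PolylineROI"))
    if (!polylineInsideImage(axisRoi@points, image@pixels, image@pixelSize))
        stop("polyline exits the image")
    if (width > 0) {
        map <- straighten(image, axisRoi, halfWidth = width / 2,
                          axialStep = step, transverseStep = step)
        intensity <- colMeans(map@grid, na.rm = TRUE)
        pos <- map@s
    } else {
        total <- arcLength(axisRoi)
        at <- seq(0, total, length.out = max(2L, floor(total / step) + 1L))
        par <- polylinePointsAt(axisRoi@points, at)
        intensity <- sampleBilinear(image@pixels, image@pixelSize,
                                    par$points[, 1L], par$points[, 2L])
        pos <- at / total
    }
    if (origin == "oral") {
        pos <- rev(1 - pos)
        intensity <- rev(intensity)
    }
    data.frame(position = pos, intensity = intensity)
}
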