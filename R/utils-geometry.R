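# Internal geometry helpers shared across modules.
#
# Physical coordinate convention: pixel [r, c] has centre
# (x, y) = ((c - 1) * ps, (r - 1) * ps).

#' @importFrom pracma interp2
sampleBilinear <- function(pixels, pixelSize, xp, yp) {
    nr <- nrow(pixels)
    nc <- ncol(pixels)
    # interp2 expects x along columns, y along rows
    pracma::interp2(
        x = (seq_len(nc) - 1) * pixelSize,
        y = (seq_len(nr) - 1) * pixelSize,
        Z = pixels, xp = xp, yp = yp, method = "linear"
    )
}

# Arc-length parameterisation of a polyline. Returns, for arc positions
# `at` (um from the start), the point p(at) and the unit tangent of the
# containing segment.
polylinePointsAt <- function(points, at) {
    seg <- diff(points)
    segLen <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(segLen))
    total <- cum[length(cum)]
    at <- pmin(pmax(at, 0), total)
    idx <- findInterval(at, cum, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(segLen))
    frac <- (at - cum[idx]) / segLen[idx]
    tang <- seg[idx, , drop = FALSE] / segLen[idx]
    pts <- points[idx, , drop = FALSE] + tang * frac * segLen[idx]
    list(points = pts, tangents = tang, total = total)
}

# TRUE when every polyline vertex lies inside the image extent.
polylineInsideImage <- function(points, pixels, pixelSize) {
    xmax <- (ncol(pixels) - 1) * pixelSize
    ymax <- (nrow(pixels) - 1) * pixelSize
    all(points[, 1] >= 0 & points[, 1] <= xmax &
        points[, 2] >= 0 & points[, 2] <= ymax)
}

# Foreground pixel centres of a mask, in um, as an n x 2 (x, y) matrix.
maskCoordinates <- function(mask) {
    idx <- which(mask@pixels > 0, arr.ind = TRUE)
    cbind(x = (idx[, "col"] - 1) * mask@pixelSize,
          y = (idx[, "row"] - 1) * mask@pixelSize)
}

# Gaussian sigma giving a stated full width at half maximum.
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
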