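#' Synthetic-scene configuration
#'
#' Parameters of the synthetic fluorescence scenes used for parameter-recovery
#' testing of every estimator in the package. Defaults emulate the imaging
#' conditions of the larva-to-polyp study system: a thin bright mesoglea band
#' of ~2 um FWHM between an ectodermal and a brighter endodermal tissue band,
#' an elongating elliptical body column, a ~5 um wide aboral collagen-IV
#' depletion zone, and stadium-shaped photoconverted patches.
#'
#' The mesoglea transverse profile is Gaussian with
#' \code{sigma = mesogleaThickness / (2 sqrt(2 ln 2))}, so its FWHM equals
#' \code{mesogleaThickness} by construction and the FWHM estimator has an
#' analytic oracle. The aboral depletion dip is a Gaussian-shaped
#' multiplicative attenuation whose full width at half depth equals
#' \code{depletionWidth}, mirroring the FWHM convention. Image noise is
#' additive Gaussian (truncated at zero, as in a photon detector);
#' volume-trace noise is multiplicative log-normal.
#'
#' @param pixelSize micrometres per pixel.
#' @param bodyLength,bodyWidth body-column ellipse axes in micrometres.
#' @param bodyAngle body axis angle in degrees (image x axis = 0).
#' @param mesogleaThickness mesoglea band FWHM in micrometres.
#' @param mesogleaPeak peak intensity of the mesoglea band above tissue.
#' @param tissueIntensity intensity of the ectodermal tissue band.
#' @param endodermExcess multiplicative intracellular signal factor (>= 1)
#'   of the endoderm relative to the ectoderm.
#' @param depletionWidth aboral depletion-zone full width at half depth, um.
#' @param depletionDepth fractional depth of the depletion dip in [0, 1].
#' @param patchLength,patchWidth overall length and width of the stadium
#'   patch, micrometres (length >= width).
#' @param patchAngle patch orientation in degrees.
#' @param noiseSigma additive Gaussian noise SD (intensity units).
#' @param margin empty margin around generated structures, micrometres.
#' @param seed integer seed; the same (config, seed) always produces
#'   bit-identical scenes.
#' @return A named list of class \code{SceneConfig}.
#' @export
sceneConfig <- function(pixelSize = 0.1,
                        bodyLength = 100, bodyWidth = 50, bodyAngle = 0,
                        mesogleaThickness = 2, mesogleaPeak = 200,
                        tissueIntensity = 10, endodermExcess = 2,
                        depletionWidth = 5, depletionDepth = 0.6,
                        patchLength = 50, patchWidth = 10, patchAngle = 30,
                        noiseSigma = 0, margin = 5, seed = 1L) {
    cfg <- list(pixelSize = pixelSize, bodyLength = bodyLength,
                bodyWidth = bodyWidth, bodyAngle = bodyAngle,
                mesogleaThickness = mesogleaThickness,
                mesogleaPeak = mesogleaPeak,
                tissueIntensity = tissueIntensity,
                endodermExcess = endodermExcess,
                depletionWidth = depletionWidth,
                depletionDepth = depletionDepth,
                patchLength = patchLength, patchWidth = patchWidth,
                patchAngle = patchAngle, noiseSigma = noiseSigma,
                margin = margin, seed = as.integer(seed))
    lengths <- c("pixelSize", "bodyLength", "bodyWidth", "mesogleaThickness",
                 "mesogleaPeak", "tissueIntensity", "depletionWidth",
                 "patchLength", "patchWidth", "margin")
    for (f in lengths)
        if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
            stop("'", f, "' must be positive")
    if (cfg$endodermExcess < 1) stop("'endodermExcess' must be >= 1")
    if (cfg$depletionDepth < 0 || cfg$depletionDepth > 1)
        stop("'depletionDepth' must lie in [0, 1]")
    if (cfg$noiseSigma < 0) stop("'noiseSigma' must be >= 0")
    if (cfg$patchLength < cfg$patchWidth)
        stop("'patchLength' must be >= 'patchWidth'")
    class(cfg) <- "SceneConfig"
    cfg
}

# Pixel-centre coordinate grids (um) for an nr x nc image.
.coordGrids <- function(nr, nc, ps) {
    list(x = matrix((seq_len(nc) - 1) * ps, nr, nc, byrow = TRUE),
         y = matrix((seq_len(nr) - 1) * ps, nr, nc))
}

.addNoise <- function(pixels, sigma) {
    if (sigma > 0)
        pixels <- pixels + matrix(stats::rnorm(length(pixels), 0, sigma),
                                  nrow(pixels))
    pmax(pixels, 0)
}

#' Generate a synthetic body-column scene
#'
#' Renders an elliptical body column at \code{bodyAngle}: an ectodermal band
#' (intensity \code{tissueIntensity}) on the negative transverse side, an
#' endodermal band (\code{tissueIntensity * endodermExcess}) on the positive
#' side, separated by a Gaussian mesoglea ridge of FWHM
#' \code{mesogleaThickness} running along the major axis. Ground truth
#' (aspect ratio, spheroid volume, midline polyline, mask) is recorded for
#' parameter-recovery tests. With the polyline oriented as generated,
#' positive transverse offsets in [straighten()] fall on the endoderm side.
#'
#' @param config a [sceneConfig()].
#' @param sceneWidth,sceneHeight optional scene extent in micrometres; by
#'   default the grid is sized to fit the rotated body plus margin, and an
#'   explicitly smaller grid is an error.
#' @return A list with elements \code{colIV} (a [CalibratedImage-class]
#'   carrying the mesoglea band between the tissue layers), \code{fActin}
#'   (a uniform cytoskeletal counterstain of the whole body, the channel to
#'   segment on), \code{mask} (a [MaskImage-class] of the body ellipse)
#'   and \code{truth} (list: the generative parameters plus \code{AR},
#'   \code{volume}, \code{midline} as a [PolylineROI-class], and the scene
#'   extent).
#' @export
makeBodyScene <- function(config, sceneWidth = NULL, sceneHeight = NULL) {
    stopifnot(inherits(config, "SceneConfig"))
    set.seed(config$seed)
    ps <- config$pixelSize
    l <- config$bodyLength; w <- config$bodyWidth
    th <- config$bodyAngle * pi / 180
    # scene extent: rotated ellipse bounding box + margin
    ex <- abs(l / 2 * cos(th)) + abs(w / 2 * sin(th)) + config$margin
    ey <- abs(l / 2 * sin(th)) + abs(w / 2 * cos(th)) + config$margin
    if (!is.null(sceneWidth) || !is.null(sceneHeight)) {
        if ((!is.null(sceneWidth) && sceneWidth < 2 * ex) ||
            (!is.null(sceneHeight) && sceneHeight < 2 * ey))
            stop("body does not fit in the requested grid")
        if (!is.null(sceneWidth)) ex <- sceneWidth / 2
        if (!is.null(sceneHeight)) ey <- sceneHeight / 2
    }
    nc <- ceiling(2 * ex / ps) + 1L
    nr <- ceiling(2 * ey / ps) + 1L
    cx <- (nc - 1) / 2 * ps
    cy <- (nr - 1) / 2 * ps
    g <- .coordGrids(nr, nc, ps)
    u <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
    v <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
    inside <- (u / (l / 2))^2 + (v / (w / 2))^2 <= 1
    sig <- fwhmToSigma(config$mesogleaThickness)
    tissue <- ifelse(v > 0, config$tissueIntensity * config$endodermExcess,
                     config$tissueIntensity)
    ridge <- config$mesogleaPeak * exp(-v^2 / (2 * sig^2))
    pixels <- ifelse(inside, tissue + ridge, 0)
    pixels <- .addNoise(pixels, config$noiseSigma)
    factin <- .addNoise(inside * 100, config$noiseSigma)
    # midline polyline along the inner 80% of the major axis (keeps the
    # transverse band inside the ellipse at both ends)
    uEnds <- c(-0.4, 0.4) * l
    mid <- cbind(x = cx + uEnds * cos(th), y = cy + uEnds * sin(th))
    list(
        colIV = CalibratedImage(pixels, ps, "ColIV"),
        fActin = CalibratedImage(factin, ps, "FActin"),
        mask = MaskImage(inside * 1, ps),
        truth = c(config, list(
            AR = l / w,
            volume = 4 / 3 * pi * (l / 2) * (w / 2)^2,
            midline = PolylineROI(mid),
            centre = c(x = cx, y = cy),
            extent = c(nr = nr, nc = nc)
        ))
    )
}

#' Generate a synthetic aboral-pole scene
#'
#' Renders a horizontal mesoglea band (on zero background) with, at the
#' pore position, a Gaussian-shaped multiplicative intensity dip of
#' depth \code{depletionDepth} and full width at half depth
#' \code{depletionWidth} in the ColIV channel, and a co-located band
#' thickening (50 percent local FWHM increase) in the Laminin channel.
#'
#' @param config a [sceneConfig()].
#' @param sceneWidth,sceneHeight scene extent in micrometres (the width must
#'   exceed \code{depletionWidth}).
#' @return List with \code{colIV} and \code{laminin}
#'   ([CalibratedImage-class]), and \code{truth} (generative parameters plus
#'   the pore position and the midline [PolylineROI-class] along the band).
#' @export
makeAboralScene <- function(config, sceneWidth = 120, sceneHeight = 40) {
    stopifnot(inherits(config, "SceneConfig"))
    if (config$depletionWidth >= sceneWidth)
        stop("depletion zone wider than the scene")
    set.seed(config$seed)
    ps <- config$pixelSize
    nc <- ceiling(sceneWidth / ps) + 1L
    nr <- ceiling(sceneHeight / ps) + 1L
    y0 <- (nr - 1) / 2 * ps
    x0 <- (nc - 1) / 2 * ps
    g <- .coordGrids(nr, nc, ps)
    sig <- fwhmToSigma(config$mesogleaThickness)
    sigD <- fwhmToSigma(config$depletionWidth)
    # the aboral band sits on zero background: the profile is taken along
    # the mesoglea itself, where the basement-membrane signal dominates, so
    # the flank level equals the undepleted band and depth is recovered
    # exactly (a depth of 1 sends the profile to zero at the pore)
    dip <- 1 - config$depletionDepth * exp(-(g$x - x0)^2 / (2 * sigD^2))
    band <- config$mesogleaPeak * exp(-(g$y - y0)^2 / (2 * sig^2))
    colIV <- .addNoise(band * dip, config$noiseSigma)
    sigLam <- sig * (1 + 0.5 * exp(-(g$x - x0)^2 / (2 * sigD^2)))
    lam <- .addNoise(config$mesogleaPeak * exp(-(g$y - y0)^2 / (2 * sigLam^2)),
                     config$noiseSigma)
    mid <- cbind(x = c(0, (nc - 1) * ps), y = c(y0, y0))
    list(
        colIV = CalibratedImage(colIV, ps, "ColIV"),
        laminin = CalibratedImage(lam, ps, "Laminin"),
        truth = c(config, list(
            porePosition = x0,   # um along the midline
            midline = PolylineROI(mid),
            bandY = y0,
            extent = c(nr = nr, nc = nc)
        ))
    )
}

#' Generate a synthetic photoconverted-patch mask
#'
#' Renders a stadium-shaped (rectangle with semicircular caps) patch of
#' overall length \code{patchLength} and width \code{patchWidth} at
#' \code{patchAngle}. The analytic truth records the stadium area
#' \code{L W - (4 - pi) (W/2)^2}, the medial-axis length \code{L - W} and
#' the implied elongation index \code{(L - W)^2 / A}.
#'
#' @param config a [sceneConfig()].
#' @return List with \code{mask} (a [MaskImage-class]) and \code{truth}.
#' @export
makePatchScene <- function(config) {
    stopifnot(inherits(config, "SceneConfig"))
    set.seed(config$seed)
    ps <- config$pixelSize
    L <- config$patchLength; W <- config$patchWidth
    th <- config$patchAngle * pi / 180
    half <- (L - W) / 2      # half-length of the medial segment
    ex <- abs(half * cos(th)) + W / 2 + config$margin
    ey <- abs(half * sin(th)) + W / 2 + config$margin
    nc <- ceiling(2 * ex / ps) + 1L
    nr <- ceiling(2 * ey / ps) + 1L
    # centre the stadium half a pixel off the grid so that its boundary
    # never aligns exactly with pixel centres (knife-edge rows would
    # otherwise bias the discretised area by half a pixel per edge)
    cx <- (nc - 1) / 2 * ps + ps / 2
    cy <- (nr - 1) / 2 * ps + ps / 2
    # 4 x 4 supersampling per pixel: a pixel is foreground when at least
    # half of its subsamples fall inside the stadium. This keeps the
    # discretised area unbiased even when the patch boundary aligns with
    # the pixel grid.
    sub <- ((0:3) + 0.5) / 4 - 0.5
    count <- matrix(0L, nr, nc)
    g <- .coordGrids(nr, nc, ps)
    for (ox in sub) for (oy in sub) {
        xs <- g$x + ox * ps
        ys <- g$y + oy * ps
        u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        du <- pmax(abs(u) - half, 0)
        count <- count + (du^2 + v^2 <= (W / 2)^2)
    }
    inside <- count >= 8L
    if (!any(inside)) stop("patch outside grid")
    area <- L * W - (4 - pi) * (W / 2)^2
    list(
        mask = MaskImage(inside * 1, ps),
        truth = c(config, list(
            area = area,
            skeletonLength = L - W,
            ARpatch = (L - W)^2 / area,
            extent = c(nr = nr, nc = nc)
        ))
    )
}

#' Trajectory-generator configuration
#'
#' @param nFrames number of frames.
#' @param dt frame interval in minutes.
#' @param ARStart,AREnd body aspect ratio at the first and last frame
#'   (linear interpolation between them).
#' @param volumeStart initial body volume, cubic micrometres.
#' @param growthRate relative volume growth per frame.
#' @param leakageFrame 1-based frame index of the abrupt leakage event, or
#'   \code{NA} for no event.
#' @param leakageFraction fractional volume lost at the event, in (0, 1).
#' @param noiseCV coefficient of variation of multiplicative log-normal
#'   volume noise.
#' @param seed integer seed.
#' @return A named list of class \code{TrajectoryConfig}.
#' @export
trajectoryConfig <- function(nFrames = 100, dt = 5, ARStart = 1.5,
                             AREnd = 8, volumeStart = 1e6,
                             growthRate = 0.005, leakageFrame = NA,
                             leakageFraction = 0.15, noiseCV = 0,
                             seed = 1L) {
    if (nFrames < 2) stop("'nFrames' must be >= 2")
    if (dt <= 0) stop("'dt' must be positive")
    if (volumeStart <= 0) stop("'volumeStart' must be positive")
    if (leakageFraction <= 0 || leakageFraction >= 1)
        stop("'leakageFraction' must lie in (0, 1)")
    if (!is.na(leakageFrame) &&
        (leakageFrame < 2 || leakageFrame > nFrames))
        stop("'leakageFrame' must lie within 2..nFrames")
    if (noiseCV < 0) stop("'noiseCV' must be >= 0")
    cfg <- list(nFrames = as.integer(nFrames), dt = dt, ARStart = ARStart,
                AREnd = AREnd, volumeStart = volumeStart,
                growthRate = growthRate,
                leakageFrame = if (is.na(leakageFrame)) NA_integer_
                               else as.integer(leakageFrame),
                leakageFraction = leakageFraction, noiseCV = noiseCV,
                seed = as.integer(seed))
    class(cfg) <- "TrajectoryConfig"
    cfg
}

#' Generate a synthetic morphospace trajectory
#'
#' Aspect ratio interpolates linearly from \code{ARStart} to \code{AREnd};
#' volume grows geometrically at \code{growthRate} per frame until the
#' leakage event (if any), at which point it drops by \code{leakageFraction}
#' and stays at the reduced value (growth is arrested by the event, matching
#' the observed developmental arrest after aboral leakage; this also makes
#' the frame-to-frame ratio at the event exactly
#' \code{1 - leakageFraction} in the noise-free case). Noise is
#' mean-one multiplicative log-normal with coefficient of variation
#' \code{noiseCV}.
#'
#' @param config a [trajectoryConfig()].
#' @return List with \code{trajectory}, a data.frame (frame, t, volume, AR),
#'   and \code{truth} (the config plus the noise-free volume trace and the
#'   AR at the leakage frame).
#' @export
makeTrajectory <- function(config) {
    stopifnot(inherits(config, "TrajectoryConfig"))
    set.seed(config$seed)
    n <- config$nFrames
    k <- seq_len(n)
    AR <- config$ARStart + (config$AREnd - config$ARStart) * (k - 1) / (n - 1)
    lf <- config$leakageFrame
    vol <- config$volumeStart * (1 + config$growthRate)^(k - 1)
    if (!is.na(lf)) {
        vPre <- config$volumeStart * (1 + config$growthRate)^(lf - 2)
        vol[k >= lf] <- vPre * (1 - config$leakageFraction)
    }
    volNoisy <- vol
    if (config$noiseCV > 0) {
        sdl <- sqrt(log(1 + config$noiseCV^2))
        volNoisy <- vol * exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
    traj <- data.frame(frame = k, t = (k - 1) * config$dt,
                       volume = volNoisy, AR = AR)
    list(trajectory = traj,
         truth = c(config, list(
             volumeClean = vol,
             ARAtLeakage = if (is.na(lf)) NA_real_ else AR[lf])))
}
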