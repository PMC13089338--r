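#' Segment the body column
#'
#' Thresholds the image (Otsu's method when \code{threshold = "auto"}), keeps
#' the largest connected foreground component and fills its holes. Tentacle
#' exclusion is the caller's responsibility: the returned mask is meant to be
#' body-column-only.
#'
#' @param image a [CalibratedImage-class].
#' @param threshold an intensity cutoff, or \code{"auto"} for Otsu.
#' @return A [MaskImage-class].
#' @importFrom EBImage otsu bwlabel fillHull
#' @export
segmentBody <- function(image, threshold = "auto") {
    stopifnot(is(image, "CalibratedImage"))
    px <- image@pixels
    mx <- max(px)
    if (mx <= 0) stop("empty foreground: image is all zero")
    thr <- if (identical(threshold, "auto"))
        EBImage::otsu(px / mx, range = c(0, 1)) * mx
    else as.numeric(threshold)
    fg <- (px > thr) * 1
    if (!any(fg > 0)) stop("empty foreground after thresholding")
    lab <- EBImage::bwlabel(fg)
    counts <- tabulate(lab[lab > 0])
    keep <- which.max(counts)
    comp <- (lab == keep) * 1
    comp <- EBImage::fillHull(comp)
    MaskImage(as.matrix(comp), image@pixelSize)
}

# principal axis (unit vector) and centroid of foreground pixel centres
.principalAxis <- function(coords) {
    ctr <- colMeans(coords)
    cc <- sweep(coords, 2, ctr)
    cov <- crossprod(cc) / nrow(cc)
    eig <- eigen(cov, symmetric = TRUE)
    axis <- eig$vectors[, 1L]
    if (axis[1L] < 0 || (axis[1L] == 0 && axis[2L] < 0)) axis <- -axis
    list(centroid = ctr, axis = axis)
}

#' Fit an axis-aligned bounding box to a body-column mask
#'
#' The oral-aboral direction is taken as the principal axis of the mask's
#' second-order moments; \code{l} and \code{w} are the extents of the
#' minimal bounding rectangle aligned to that axis (pixel footprints
#' included, i.e. extent of centres + one pixel). The orientation tie-break
#' guarantees \code{l >= w}, so \code{AR = l / w >= 1}.
#'
#' @param mask a [MaskImage-class] containing the body column only
#'   (tentacles removed upstream).
#' @return A [BodyShape-class] with \code{volume = NA}; apply
#'   [estimateVolume()] to fill it.
#' @export
fitBoundingBox <- function(mask) {
    stopifnot(is(mask, "MaskImage"))
    coords <- maskCoordinates(mask)
    if (nrow(coords) == 0L) stop("empty mask")
    if (nrow(coords) == 1L) stop("single-pixel mask: axis undefined")
    pa <- .principalAxis(coords)
    ax <- pa$axis
    perp <- c(-ax[2L], ax[1L])
    u <- as.vector(coords %*% ax)
    v <- as.vector(coords %*% perp)
    ps <- mask@pixelSize
    l <- diff(range(u)) + ps
    w <- diff(range(v)) + ps
    ang <- atan2(ax[2L], ax[1L]) * 180 / pi
    if (l < w) {
        tmp <- l; l <- w; w <- tmp
        ang <- ang + 90
    }
    ang <- ((ang + 90) %% 180) - 90
    new("BodyShape", l = l, w = w, AR = l / w, volume = NA_real_,
        axisAngle = ang)
}

#' Solid-of-revolution volume of a body-column mask
#'
#' Resamples the mask into the principal-axis frame and integrates
#' \code{sum(pi * r(s)^2 * ds)} where \code{r(s)} is half the local
#' transverse extent of each axial slice (one pixel per slice). The
#' revolution model is justified by the radial symmetry of the body plan.
#'
#' @param mask a [MaskImage-class].
#' @param shape optional [BodyShape-class] from [fitBoundingBox()] (computed
#'   if missing); its volume slot is filled in the returned object.
#' @return The input \code{shape} with \code{volume} set (um^3).
#' @export
estimateVolume <- function(mask, shape = NULL) {
    stopifnot(is(mask, "MaskImage"))
    if (is.null(shape)) shape <- fitBoundingBox(mask)
    coords <- maskCoordinates(mask)
    if (nrow(coords) < 2L) stop("degenerate axis: not enough foreground")
    th <- shape@axisAngle * pi / 180
    ax <- c(cos(th), sin(th))
    perp <- c(-ax[2L], ax[1L])
    u <- as.vector(coords %*% ax)
    v <- as.vector(coords %*% perp)
    ps <- mask@pixelSize
    slice <- floor((u - min(u)) / ps + 0.5)
    rng <- vapply(split(v, slice),
                  function(z) diff(range(z)) + ps, numeric(1))
    vol <- sum(pi * (rng / 2)^2 * ps)
    initialize(shape, volume = vol)
}

#' Assemble a morphospace trajectory from per-frame shapes
#'
#' Stores the raw per-frame volume and aspect ratio and a rolling-median
#' smoothed volume trace (window \code{smoothWindow}, default 5; window 1 is
#' the identity) used only for event detection.
#'
#' @param shapes list of [BodyShape-class] (time-ordered, volumes set), or a
#'   data.frame with columns \code{volume} and \code{AR}.
#' @param times frame times in minutes, strictly increasing.
#' @param smoothWindow odd rolling-median window (frames).
#' @return A [MorphospaceTrajectory-class] with no events; run
#'   [detectLeakageOnset()] to populate them.
#' @importFrom stats runmed
#' @export
buildTrajectory <- function(shapes, times, smoothWindow = 5L) {
    if (is.data.frame(shapes)) {
        vol <- shapes$volume
        AR <- shapes$AR
    } else {
        vol <- vapply(shapes, function(s) s@volume, numeric(1))
        AR <- vapply(shapes, function(s) s@AR, numeric(1))
    }
    n <- length(vol)
    if (n < 2L) stop("need at least 2 frames")
    if (length(times) != n) stop("times must match the number of frames")
    if (any(diff(times) <= 0))
        stop("times must be strictly increasing (duplicates not allowed)")
    smoothWindow <- as.integer(smoothWindow)
    if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
        stop("'smoothWindow' must be a positive odd integer")
    sm <- if (smoothWindow == 1L) vol
          else as.numeric(stats::runmed(vol, smoothWindow,
                                        endrule = "median"))
    fr <- data.frame(frame = seq_len(n), t = times, volume = vol, AR = AR,
                     volumeSmooth = sm)
    new("MorphospaceTrajectory", frames = fr,
        events = data.frame(frame = integer(), kind = character(),
                            dropFraction = numeric(),
                            ARAtOnset = numeric()))
}

#' Detect abrupt leakage events on a volume trace
#'
#' A leakage event is declared at the first frame \code{k} where the
#' smoothed volume has fallen by at least \code{dropThreshold} relative to
#' the maximum smoothed volume over the preceding \code{window} frames.
#' After an event, detection re-arms only once the smoothed volume exceeds
#' its value at the previous event again (a new running maximum), so a
#' single sustained drop yields a single event. Each event reports the
#' fractional drop and the body aspect ratio at onset.
#'
#' @param traj a [MorphospaceTrajectory-class].
#' @param dropThreshold minimum fractional drop (default 0.10).
#' @param window number of preceding frames forming the reference maximum
#'   (default 3).
#' @return The trajectory with its \code{events} slot populated
#'   (possibly empty; no event is not an error).
#' @export
detectLeakageOnset <- function(traj, dropThreshold = 0.10, window = 3L) {
    stopifnot(is(traj, "MorphospaceTrajectory"))
    if (dropThreshold <= 0 || dropThreshold >= 1)
        stop("'dropThreshold' must lie in (0, 1)")
    fr <- traj@frames
    n <- nrow(fr)
    window <- as.integer(window)
    if (n < window + 1L) stop("trajectory shorter than window + 1 frames")
    v <- fr$volumeSmooth
    events <- list()
    armed <- TRUE
    refAtEvent <- -Inf
    for (k in seq.int(2L, n)) {
        lo <- max(1L, k - window)
        ref <- max(v[lo:(k - 1L)])
        if (!armed && v[k] > refAtEvent) armed <- TRUE
        if (armed && ref > 0 && v[k] <= (1 - dropThreshold) * ref) {
            events[[length(events) + 1L]] <- data.frame(
                frame = k, kind = "leakage",
                dropFraction = 1 - v[k] / ref,
                ARAtOnset = fr$AR[k])
            armed <- FALSE
            refAtEvent <- ref
        }
    }
    ev <- if (length(events)) do.call(rbind, events)
          else traj@events[0, ]
    initialize(traj, events = ev)
}
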