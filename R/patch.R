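# Zhang-Suen morphological thinning on a 0/1 matrix. Vectorised over the
# whole grid; iterates the two sub-steps until no pixel changes.
zhangSuenThin <- function(m) {
    p <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
    p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    nr <- nrow(p); nc <- ncol(p)
    shift <- function(z, dr, dc) {
        out <- matrix(0, nr, nc)
        rs <- max(1L, 1L + dr):min(nr, nr + dr)
        cs <- max(1L, 1L + dc):min(nc, nc + dc)
        out[rs, cs] <- z[rs - dr, cs - dc]
        out
    }
    repeat {
        changed <- FALSE
        for (step in 1:2) {
            # neighbours P2..P9 clockwise from north
            P2 <- shift(p, 1, 0);  P3 <- shift(p, 1, -1)
            P4 <- shift(p, 0, -1); P5 <- shift(p, -1, -1)
            P6 <- shift(p, -1, 0); P7 <- shift(p, -1, 1)
            P8 <- shift(p, 0, 1);  P9 <- shift(p, 1, 1)
            B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
            A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) +
                 (P4 == 0 & P5 == 1) + (P5 == 0 & P6 == 1) +
                 (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
                 (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
            cond <- p == 1 & B >= 2 & B <= 6 & A == 1
            if (step == 1)
                cond <- cond & (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
            else
                cond <- cond & (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
            if (any(cond)) {
                p[cond] <- 0
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
}

# Longest geodesic path (um) on the 8-connected skeleton graph.
# The path is selected by double-sweep Dijkstra with {1, sqrt(2)} edge
# weights (farthest node from an arbitrary start, then farthest from that;
# exact on trees, which pruned skeletons effectively are; ties break to the
# lowest node index for determinism). Its length is then measured with the
# Vossepoel-Smeulders chain-code estimator
#   L = (0.980 Ne + 1.406 No - 0.091 Nc) * pixelSize
# (Ne axial steps, No diagonal steps, Nc direction changes), which bounds
# the staircase error of digital straight lines to about 1 percent where
# raw {1, sqrt(2)} weights overestimate oblique curves by up to 8 percent.
# Finally, because morphological thinning retracts skeleton endpoints away
# from the true medial-axis tips, each end is extended along its local
# direction to the mask boundary minus the local half-width (taken from the
# Euclidean distance map): for an elongated patch this reconstructs exactly
# the retracted portion.
#' @importFrom igraph graph_from_data_frame distances shortest_paths
skeletonLongestPath <- function(skel, pixelSize, mask = NULL) {
    idx <- which(skel == 1)
    if (length(idx) < 2L) return(0)
    nr <- nrow(skel)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    lookup <- integer(length(skel))
    lookup[idx] <- seq_along(idx)
    edges <- list()
    wts <- list()
    moves <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                  c(1L, -1L, sqrt(2)))
    for (mv in moves) {
        r2 <- rr + mv[1L]; c2 <- cc + mv[2L]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
        j <- (c2[ok] - 1L) * nr + r2[ok]
        hit <- lookup[j] > 0L
        if (any(hit)) {
            edges[[length(edges) + 1L]] <-
                cbind(which(ok)[hit], lookup[j[hit]])
            wts[[length(wts) + 1L]] <- rep(mv[3L] * pixelSize, sum(hit))
        }
    }
    if (!length(edges)) return(0)
    ed <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(
        data.frame(from = ed[, 1L], to = ed[, 2L], weight = unlist(wts)),
        directed = FALSE,
        vertices = data.frame(name = seq_along(idx)))
    d1 <- igraph::distances(g, v = 1)[1L, ]
    d1[!is.finite(d1)] <- -1
    a <- which.max(d1)
    d2 <- igraph::distances(g, v = a)[1L, ]
    d2[!is.finite(d2)] <- -1
    b <- which.max(d2)
    path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1L]]
    pid <- as.integer(names(path))
    pr <- rr[pid]; pc <- cc[pid]
    if (length(pid) < 2L) return(0)
    dr <- diff(pr); dc <- diff(pc)
    diag <- abs(dr) == 1L & abs(dc) == 1L
    dirs <- paste(dr, dc)
    nCorner <- sum(dirs[-1L] != dirs[-length(dirs)])
    len <- (0.980 * sum(!diag) + 1.406 * sum(diag) -
            0.091 * nCorner) * pixelSize
    if (!is.null(mask))
        len <- len +
            .endpointExtension(pr, pc, mask, pixelSize) +
            .endpointExtension(rev(pr), rev(pc), mask, pixelSize)
    len
}

# Extension (um) of the path's first endpoint: ray-march from the endpoint
# along the outward local path direction until leaving the mask, then
# subtract the local half-width (distance-map value at the endpoint).
.endpointExtension <- function(pr, pc, mask, pixelSize) {
    n <- length(pr)
    m <- min(n, 8L)
    v <- c(pr[1L] - pr[m], pc[1L] - pc[m])
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
    halfWidth <- .distmapAt(mask, pr[1L], pc[1L]) # px
    t <- 0
    repeat {
        t <- t + 0.5
        ri <- as.integer(round(pr[1L] + v[1L] * t))
        ci <- as.integer(round(pc[1L] + v[2L] * t))
        if (ri < 1L || ri > nrow(mask) || ci < 1L || ci > ncol(mask) ||
            mask[ri, ci] == 0) break
        if (t > max(dim(mask))) break
    }
    max(0, (t - 0.5) - halfWidth) * pixelSize
}

.distmapAt <- function(mask, r, c) {
    dm <- EBImage::distmap(mask)
    as.numeric(dm[r, c])
}

#' Elongation metrics of a photoconverted patch
#'
#' Computes area \code{A} (foreground pixels times pixel area), skeleton
#' length \code{l} (longest geodesic path through the morphologically
#' thinned mask, which inherently discards short side spurs), empirical
#' width \code{w = A / l}, and the elongation index
#' \code{ARpatch = l^2 / A = l / w}. Near-circular patches whose skeleton
#' collapses towards a point yield \code{ARpatch < 1} with a
#' degenerate-skeleton warning.
#'
#' @param mask a [MaskImage-class] containing exactly one connected patch of
#'   at least \code{minArea} pixels.
#' @param minArea minimum foreground pixel count.
#' @return A [PatchShape-class].
#' @export
patchMetrics <- function(mask, minArea = 25L) {
    stopifnot(is(mask, "MaskImage"))
    px <- mask@pixels
    nfg <- sum(px)
    if (nfg == 0) stop("empty mask")
    lab <- EBImage::bwlabel(px)
    if (max(lab) > 1L)
        stop("mask has ", max(lab), " connected components; expected 1")
    if (nfg < minArea)
        stop("patch smaller than the minimum area (", minArea, " px)")
    ps <- mask@pixelSize
    A <- nfg * ps^2
    skel <- zhangSuenThin(px)
    l <- skeletonLongestPath(skel, ps, mask = px)
    degen <- l < 2 * ps
    if (degen)
        warning("degenerate skeleton: patch is near-circular, ",
                "skeleton length unreliable")
    w <- if (l > 0) A / l else NA_real_
    new("PatchShape", A = A, l = l, w = w,
        ARpatch = l^2 / A, inverted = FALSE, degenerate = degen)
}

#' Invert a patch aspect ratio
#'
#' When a patch's shape inverted during axial elongation (a caller-supplied
#' judgement; there is no automatic criterion), the elongation index is
#' replaced by its reciprocal and the \code{inverted} flag is toggled.
#' Applying the inversion twice restores the original value exactly.
#'
#' @param shape a [PatchShape-class] with positive \code{ARpatch}.
#' @param invert logical.
#' @return The (possibly) inverted [PatchShape-class].
#' @export
applyInversion <- function(shape, invert) {
    stopifnot(is(shape, "PatchShape"), is.logical(invert))
    if (!invert) return(shape)
    if (shape@ARpatch <= 0) stop("cannot invert a non-positive aspect ratio")
    initialize(shape, ARpatch = 1 / shape@ARpatch,
               inverted = !shape@inverted)
}

#' Pair patch and body aspect ratios per timepoint
#'
#' Joins patch elongation and body-column aspect ratio on exactly matching
#' timepoints for trend analysis (patch AR versus body AR across
#' elongation).
#'
#' @param patches data.frame with columns \code{t} and \code{ARpatch}, or a
#'   named list of [PatchShape-class] keyed by timepoint.
#' @param bodies data.frame with columns \code{t} and \code{AR}, or a named
#'   list of [BodyShape-class] keyed by timepoint.
#' @return data.frame with columns \code{t}, \code{ARpatch}, \code{ARbody},
#'   ordered by \code{t}.
#' @export
patchVsBody <- function(patches, bodies) {
    if (!is.data.frame(patches))
        patches <- data.frame(
            t = as.numeric(names(patches)),
            ARpatch = vapply(patches, function(p) p@ARpatch, numeric(1)))
    if (!is.data.frame(bodies))
        bodies <- data.frame(
            t = as.numeric(names(bodies)),
            AR = vapply(bodies, function(b) b@AR, numeric(1)))
    if (!setequal(patches$t, bodies$t))
        stop("unmatched timepoints between patches and bodies")
    m <- merge(patches[, c("t", "ARpatch")],
               data.frame(t = bodies$t, ARbody = bodies$AR), by = "t")
    m[order(m$t), , drop = FALSE]
}
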