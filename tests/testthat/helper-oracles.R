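# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Exhaustive rotating-calipers aspect ratio on the boundary pixels of a
# mask: scans orientations brute-force and reports the extent-maximising
# rectangle's aspect ratio (pixel footprint included).
caliperAR <- function(mask, stepDeg = 0.25) {
    px <- pixels(mask)
    ps <- pixelSize(mask)
    idx <- which(px > 0, arr.ind = TRUE)
    # boundary pixels: foreground with at least one 4-neighbour background
    nr <- nrow(px); nc <- ncol(px)
    pad <- matrix(0, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- px
    nb <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
          pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
    bd <- which(px > 0 & nb < 4, arr.ind = TRUE)
    x <- (bd[, "col"] - 1) * ps
    y <- (bd[, "row"] - 1) * ps
    best <- c(-Inf, NA)
    for (th in seq(0, 180 - stepDeg, by = stepDeg) * pi / 180) {
        u <- x * cos(th) + y * sin(th)
        ext <- diff(range(u)) + ps
        if (ext > best[1]) best <- c(ext, th)
    }
    th <- best[2]
    v <- -x * sin(th) + y * cos(th)
    (best[1]) / (diff(range(v)) + ps)
}

# Monte-Carlo permutation two-sided p-value for the Mann-Whitney U,
# doubled-smaller-tail convention, matching compareGroups' definition.
permutationWilcoxP <- function(a, b, nPerm = 1e5, seed = 42) {
    set.seed(seed)
    pooled <- c(a, b)
    na <- length(a); n <- length(pooled)
    r <- rank(pooled)
    uOf <- function(ix) sum(r[ix]) - na * (na + 1) / 2
    u0 <- uOf(seq_len(na))
    us <- replicate(nPerm, uOf(sample.int(n, na)))
    pLo <- mean(us <= u0 + 1e-9)
    pHi <- mean(us >= u0 - 1e-9)
    min(1, 2 * min(pLo, pHi))
}

# Independent full-enumeration two-sided Wilcoxon p (recursion-free,
# straightforward combn over observed values rather than ranks).
enumWilcoxP <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    cmb <- utils::combn(length(pooled), na)
    uvals <- apply(cmb, 2, function(ix) {
        g1 <- pooled[ix]; g2 <- pooled[-ix]
        sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
    })
    u0 <- uvals[1]  # first column of combn is 1..na = observed assignment
    pLo <- mean(uvals <= u0 + 1e-9)
    pHi <- mean(uvals >= u0 - 1e-9)
    min(1, 2 * min(pLo, pHi))
}

# Concentric-ring test image: Gaussian annulus of radius R and sigma s.
ringImage <- function(n = 601, ps = 0.2, R = 40, sigma = 1.5, peak = 100) {
    ctr <- (n - 1) / 2
    X <- matrix(rep((0:(n - 1)) - ctr, each = n), n) * ps
    Y <- t(X)
    rr <- sqrt(X^2 + Y^2)
    list(image = CalibratedImage(exp(-(rr - R)^2 / (2 * sigma^2)) * peak,
                                 ps, "ring"),
         centre = ctr * ps, R = R)
}

# Semicircular polyline of radius R about (cx, cy).
semicircleROI <- function(cx, cy, R, nPoints = 181) {
    ang <- seq(0, pi, length.out = nPoints)
    PolylineROI(cbind(cx + R * cos(ang), cy + R * sin(ang)))
}

# Same-definition ec/ic oracle evaluated on the analytic (continuous)
# transverse profile of a body scene, densely sampled.
analyticEcIcOracle <- function(tissue, excess, peak, fwhmUm, halfWidth,
                               band, step = 0.01) {
    d <- seq(-halfWidth, halfWidth, by = step)
    sig <- fwhmUm / (2 * sqrt(2 * log(2)))
    prof <- peak * exp(-d^2 / (2 * sig^2)) +
        ifelse(d > 0, tissue * excess, tissue)
    n <- length(d)
    k <- max(1, floor(0.1 * n))
    base <- mean(c(prof[1:k], prof[(n - k + 1):n]))
    y <- prof - base
    im <- which.max(y)
    half <- y[im] / 2
    lf <- stats::approx(y[1:im], d[1:im], xout = half, ties = "ordered")$y
    rt <- stats::approx(rev(y[im:n]), rev(d[im:n]), xout = half,
                        ties = "ordered")$y
    num <- mean(prof[d >= lf & d <= rt] - base)
    den <- mean(prof[d >= band[1] & d <= band[2]])
    num / den
}

# Write a small TIFF carrying real resolution tags via the pre-installed
# Python tifffile, for testing tag-based calibration passthrough.
writeTaggedTIFF <- function(path, nr = 64, nc = 64, pxPerUm = 2) {
    script <- sprintf(paste0(
        "import numpy as np, tifffile\n",
        "img = (np.arange(%d*%d, dtype=np.float32).reshape(%d, %d)) / (%d*%d)\n",
        "tifffile.imwrite(r'%s', img, resolution=(%g, %g), resolutionunit='NONE')\n"),
        nr, nc, nr, nc, nr, nc, path, pxPerUm, pxPerUm)
    tmp <- tempfile(fileext = ".py")
    writeLines(script, tmp)
    status <- suppressWarnings(system2("python", tmp, stdout = FALSE,
                                       stderr = FALSE))
    identical(status, 0L)
}
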