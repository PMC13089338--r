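test_that("straightening a straight horizontal ROI equals the axis-aligned crop", {
    set.seed(3)
    img <- CalibratedImage(matrix(runif(60 * 80), 60, 80), 0.5)
    roi <- PolylineROI(cbind(x = c(2, 30), y = c(10, 10)))
    mp <- straighten(img, roi, halfWidth = 3, axialStep = 0.5,
                     transverseStep = 0.5)
    crop <- pixels(img)[21 + (-6:6), 5:61]
    expect_equal(max(abs(mp@grid - crop)), 0)
    expect_equal(range(mp@s), c(0, 1))
    expect_equal(mp@d, seq(-3, 3, by = 0.5))
})

test_that("straightening a vertical ROI equals the rotated crop", {
    set.seed(4)
    img <- CalibratedImage(matrix(runif(80 * 60), 80, 60), 0.5)
    roi <- PolylineROI(cbind(x = c(10, 10), y = c(2, 30)))
    mp <- straighten(img, roi, halfWidth = 2, axialStep = 0.5,
                     transverseStep = 0.5)
    # travel +y; left of travel is +x... with image y down, normal (-ty, tx)
    # = (-1, 0): positive d decreases x
    crop <- t(pixels(img)[5:61, 21 - (-4:4)])
    expect_equal(max(abs(t(mp@grid) - t(crop))), 0)
})

test_that("ring symmetry: per-position transverse profiles agree along a semicircular ROI", {
    rg <- ringImage()
    roi <- semicircleROI(rg$centre, rg$centre, rg$R)
    mp <- straighten(rg$image, roi, halfWidth = 6)
    p1 <- transverseProfile(mp, c(0.05, 0.15))
    p2 <- transverseProfile(mp, c(0.70, 0.80))
    expect_lt(max(abs(p1$intensity - p2$intensity)) / max(p1$intensity),
              0.03)
    # straightening conserves the integrated band intensity: compare the
    # map integral with the direct image integral over the half annulus
    # (curvature radius R ~ 7x half width)
    ps <- pixelSize(rg$image)
    dS <- mp@arcLength * diff(mp@s[1:2])
    dD <- diff(mp@d[1:2])
    mapIntegral <- sum(mp@grid, na.rm = TRUE) * dS * dD
    n <- nrow(pixels(rg$image))
    X <- matrix(rep((0:(n - 1)) * ps - rg$centre, each = n), n)
    Y <- t(X)
    rr <- sqrt(X^2 + Y^2)
    inBand <- abs(rr - rg$R) <= 6 & Y >= 0
    imgIntegral <- sum(pixels(rg$image)[inBand]) * ps^2
    expect_lt(abs(mapIntegral / imgIntegral - 1), 0.05)
})

test_that("straighten validates its inputs", {
    img <- CalibratedImage(matrix(1, 20, 20), 1)
    inside <- PolylineROI(cbind(c(2, 15), c(10, 10)))
    expect_error(straighten(img, inside, halfWidth = 0), "halfWidth")
    outside <- PolylineROI(cbind(c(2, 40), c(10, 10)))
    expect_error(straighten(img, outside, 2), "exits")
    # out-of-image band samples are NA, not zero
    edge <- PolylineROI(cbind(c(2, 15), c(1, 1)))
    mp <- straighten(img, edge, halfWidth = 5)
    expect_true(anyNA(mp@grid))
    expect_false(any(mp@grid == 0, na.rm = TRUE))
})

test_that("transverse profiles average over s and respect sRange", {
    img <- CalibratedImage(matrix(7, 40, 40), 1)
    roi <- PolylineROI(cbind(c(5, 30), c(20, 20)))
    mp <- straighten(img, roi, halfWidth = 4)
    pr <- transverseProfile(mp)
    expect_true(all(pr$intensity == 7))
    expect_error(transverseProfile(mp, c(2, 3)), "empty")
    # body scene: peak lies at d = 0 within one transverse step
    sc <- makeBodyScene(sceneConfig(pixelSize = 0.2, bodyLength = 40,
                                    bodyWidth = 20, seed = 5))
    mp2 <- straighten(sc$colIV, sc$truth$midline, halfWidth = 6)
    pk <- fwhm(transverseProfile(mp2))
    expect_lt(abs(pk$center), 0.2 + 1e-9)
})

test_that("fwhm matches closed forms and is affine invariant", {
    d <- seq(-10, 10, by = 0.02)
    # Gaussian, sigma 1: FWHM = 2 sqrt(2 ln 2)
    g <- exp(-d^2 / 2)
    expect_lt(abs(fwhm(d, g)$width / (2 * sqrt(2 * log(2))) - 1), 0.01)
    # symmetric triangle reaching zero at +-2: FWHM exactly 2
    tri <- pmax(0, 1 - abs(d) / 2)
    expect_equal(fwhm(d, tri)$width, 2, tolerance = 1e-12)
    # affine invariance is exact by construction
    f1 <- fwhm(d, g)
    f2 <- fwhm(d, 37 * g + 11)
    expect_equal(f2$width, f1$width, tolerance = 1e-12)
    expect_equal(f2$center, f1$center, tolerance = 1e-12)
    # error contracts
    expect_error(fwhm(d, rep(1, length(d))), "no peak")
    expect_error(fwhm(d, d - min(d)), "boundary|bracketed|significant")
})

test_that("thickness recovery across the column, tapered bands, noise", {
    for (Tt in c(1, 2, 4)) {
        cfg <- sceneConfig(pixelSize = 0.1, bodyLength = 60, bodyWidth = 30,
                           mesogleaThickness = Tt, seed = 3)
        sc <- makeBodyScene(cfg)
        mp <- straighten(sc$colIV, sc$truth$midline, halfWidth = 8)
        tc <- thicknessAlongColumn(mp)
        expect_lt(abs(tc$summary$meanThickness / Tt - 1), 0.05)
        expect_lt(tc$summary$sdThickness / tc$summary$meanThickness, 0.05)
    }
    # noise: mean over 20 seeds within 10% (5% of peak noise)
    rec <- vapply(1:20, function(s) {
        cfg <- sceneConfig(pixelSize = 0.1, bodyLength = 60, bodyWidth = 30,
                           mesogleaThickness = 2, noiseSigma = 10, seed = s)
        sc <- makeBodyScene(cfg)
        mp <- straighten(sc$colIV, sc$truth$midline, halfWidth = 8)
        thicknessAlongColumn(mp)$summary$meanThickness
    }, numeric(1))
    expect_lt(abs(mean(rec) / 2 - 1), 0.10)
    # pure-noise map: all positions undefined
    set.seed(1)
    noise <- CalibratedImage(matrix(runif(120 * 240), 120, 240), 0.5)
    roiN <- PolylineROI(cbind(c(10, 100), c(30, 30)))
    mpN <- straighten(noise, roiN, halfWidth = 10)
    expect_error(thicknessAlongColumn(mpN, bin = 1e6), "no axial position")
})

test_that("ec/ic ratio recovers the analytic oracle and is scale invariant", {
    cfg <- sceneConfig(pixelSize = 0.1, bodyLength = 60, bodyWidth = 30,
                       tissueIntensity = 50, mesogleaPeak = 200,
                       endodermExcess = 2, seed = 5)
    sc <- makeBodyScene(cfg)
    mp <- straighten(sc$colIV, sc$truth$midline, halfWidth = 8)
    got <- ecIcRatio(mp, endodermBand = c(3, 7))
    oracle <- analyticEcIcOracle(tissue = 50, excess = 2, peak = 200,
                                 fwhmUm = 2, halfWidth = 8, band = c(3, 7))
    expect_lt(abs(got$ratio / oracle - 1), 0.10)
    # multiplying the image rescales nothing
    img2 <- CalibratedImage(pixels(sc$colIV) * 3.7, 0.1, "ColIV")
    mp2 <- straighten(img2, sc$truth$midline, halfWidth = 8)
    expect_equal(ecIcRatio(mp2, c(3, 7))$ratio, got$ratio,
                 tolerance = 1e-9)
    # band overlapping the mesoglea window is rejected
    expect_error(ecIcRatio(mp, c(0.5, 3)), "overlaps")
})

test_that("axial intensity profile: gradients, reversal, origin convention", {
    n <- 50
    grad <- CalibratedImage(matrix(rep(seq(0, 98, by = 2), each = n), n),
                            1)
    roi <- PolylineROI(cbind(c(2, 40), c(25, 25)))
    pr <- axialIntensityProfile(grad, roi)
    expect_equal(pr$intensity[1], 4)                 # x = 2 -> col 3
    expect_equal(pr$intensity[nrow(pr)], 80)
    expect_lt(max(abs(diff(pr$intensity) - diff(pr$intensity)[1])), 1e-9)
    # reversed polyline, same flag: profile reversed sample-for-sample
    rev_roi <- PolylineROI(cbind(c(40, 2), c(25, 25)))
    pr2 <- axialIntensityProfile(grad, rev_roi)
    expect_equal(pr2$intensity, rev(pr$intensity))
    # oral origin flips the axis
    pr3 <- axialIntensityProfile(grad, roi, origin = "oral")
    expect_equal(pr3$intensity, rev(pr$intensity))
    # constant image: flat
    cst <- CalibratedImage(matrix(5, 30, 30), 1)
    roiC <- PolylineROI(cbind(c(2, 25), c(15, 15)))
    expect_true(all(axialIntensityProfile(cst, roiC)$intensity == 5))
})
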