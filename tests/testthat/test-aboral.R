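test_that("aboral profiles are pore-centred and track constructed structure", {
    # constant image: flat profile at the constant
    cst <- CalibratedImage(matrix(3, 200, 600), 0.5)
    line <- PolylineROI(cbind(c(10, 280), c(50, 50)))
    p <- extractAboralProfile(cst, line, porePosition = 135,
                              roiLength = 100, lineWidth = 5)
    expect_true(all(abs(p@intensity - 3) < 1e-9))
    expect_true(min(p@positions) <= 0 && max(p@positions) >= 0)
    expect_lt(diff(range(p@positions)) - 100, 1e-6)

    # step image: transition at position 0 within one sampling step
    px <- matrix(1, 200, 600)
    px[, 271:600] <- 9   # step at x = 135
    stepImg <- CalibratedImage(px, 0.5)
    # pore stated as arc length along the line (line starts at x = 10, so
    # the step at x = 135 sits at arc position 125)
    ps <- extractAboralProfile(stepImg, line, porePosition = 125,
                               roiLength = 100, lineWidth = 5)
    mid <- (1 + 9) / 2
    crossing <- ps@positions[min(which(ps@intensity > mid))]
    expect_lt(abs(crossing), 0.5 + 1e-9)

    # synthetic aboral scene: ColIV minimum at the pore within 0.5 um
    sc <- makeAboralScene(sceneConfig(pixelSize = 0.1, seed = 6))
    pc <- extractAboralProfile(sc$colIV, sc$truth$midline,
                               sc$truth$porePosition, lineWidth = 2)
    expect_lt(abs(pc@positions[which.min(pc@intensity)]), 0.5)

    # error contracts
    expect_error(extractAboralProfile(cst, line, porePosition = 500),
                 "outside")
    shortLine <- PolylineROI(cbind(c(10, 40), c(50, 50)))
    expect_error(extractAboralProfile(cst, shortLine, 15, roiLength = 100),
                 "shorter")
})

test_that("depletion width and depth recover generator truth, errors on flat", {
    sc <- makeAboralScene(sceneConfig(pixelSize = 0.1, depletionWidth = 5,
                                      depletionDepth = 0.6, seed = 2))
    p <- extractAboralProfile(sc$colIV, sc$truth$midline,
                              sc$truth$porePosition, lineWidth = 2)
    dz <- depletionZoneWidth(p)
    expect_lt(abs(dz$width - 5), 0.2)
    expect_lt(abs(dz$depth - 0.6), 0.02)
    # gain/offset invariance of the width; gain invariance of the depth
    p2 <- new("AboralProfile", positions = p@positions,
              intensity = 2.5 * p@intensity + 40, channel = p@channel,
              roiLength = p@roiLength, lineWidth = p@lineWidth)
    dz2 <- depletionZoneWidth(p2)
    expect_equal(dz2$width, dz$width, tolerance = 1e-9)
    p3 <- new("AboralProfile", positions = p@positions,
              intensity = 2.5 * p@intensity, channel = p@channel,
              roiLength = p@roiLength, lineWidth = p@lineWidth)
    expect_equal(depletionZoneWidth(p3)$depth, dz$depth, tolerance = 1e-9)
    # flat profile: no dip
    flat <- new("AboralProfile", positions = seq(-50, 50, 0.5),
                intensity = rep(10, 201), channel = "ColIV",
                roiLength = 100, lineWidth = 5)
    expect_error(depletionZoneWidth(flat), "no dip")
})

test_that("noisy depletion width recovers within 10% over 20 seeds", {
    ws <- vapply(1:20, function(s) {
        sc <- makeAboralScene(sceneConfig(pixelSize = 0.1,
                                          depletionWidth = 5,
                                          depletionDepth = 0.6,
                                          noiseSigma = 10, seed = s))
        p <- extractAboralProfile(sc$colIV, sc$truth$midline,
                                  sc$truth$porePosition, lineWidth = 2)
        depletionZoneWidth(p)$width
    }, numeric(1))
    expect_lt(abs(mean(ws) / 5 - 1), 0.10)
})

test_that("pErk profile spans 0-50 um outside-in with width averaging", {
    n <- 300
    grad <- CalibratedImage(matrix(rep(seq_len(n) - 1, each = n), n) * 0.5,
                            0.5, "pErk")
    line <- PolylineROI(cbind(c(20, 90), c(70, 70)))
    pp <- perkProfile(grad, line)
    expect_equal(range(pp@positions), c(0, 50))
    # linear inward gradient stays linear over the span
    expect_lt(max(abs(diff(pp@intensity) - diff(pp@intensity)[1])), 1e-6)
    expect_equal(pp@lineWidth, 5)
    # wider averaging reduces per-position variance on a noisy image
    set.seed(10)
    noisy <- CalibratedImage(matrix(100 + rnorm(n * n, 0, 20), n), 0.5,
                             "pErk")
    v5 <- var(perkProfile(noisy, line, lineWidth = 5)@intensity)
    v1 <- var(perkProfile(noisy, line, lineWidth = 1)@intensity)
    expect_lt(v5, v1)
    shortLine <- PolylineROI(cbind(c(20, 40), c(70, 70)))
    expect_error(perkProfile(grad, shortLine), "shorter")
})

test_that("profile ensembles align, average, and spread correctly", {
    mk <- function(val, n = 101) new("AboralProfile",
        positions = seq(-50, 50, length.out = n),
        intensity = rep(val, n), channel = "ColIV",
        roiLength = 100, lineWidth = 5)
    # six identical profiles: mean = member, SD = 0
    e6 <- ensembleProfiles(replicate(6, mk(7), simplify = FALSE))
    expect_true(all(e6@mean == 7))
    expect_true(all(e6@sd == 0))
    # two flat profiles at 10 and 20: mean 15, SD = 5 sqrt(2) ~ 7.071
    e2 <- ensembleProfiles(list(mk(10), mk(20)))
    expect_true(all(e2@mean == 15))
    expect_equal(unique(e2@sd), sqrt(50), tolerance = 1e-12)
    # single profile: SD defined as 0
    e1 <- ensembleProfiles(list(mk(4)))
    expect_true(all(e1@sd == 0))
    # mismatched channels and disjoint ranges are rejected
    other <- mk(5)
    other@channel <- "Laminin"
    expect_error(ensembleProfiles(list(mk(1), other)), "channel")
    far <- mk(5)
    far@positions <- far@positions + 1000
    expect_error(ensembleProfiles(list(mk(1), far)), "overlap")
    # ensemble agrees with direct per-position formulas on a shared grid
    set.seed(2)
    mats <- replicate(5, mk(0), simplify = FALSE)
    for (i in seq_along(mats))
        mats[[i]]@intensity <- rnorm(101, mean = 50, sd = 4)
    ee <- ensembleProfiles(mats)
    direct <- sapply(seq_len(101), function(j)
        mean(vapply(mats, function(m) m@intensity[j], numeric(1))))
    expect_equal(ee@mean, direct, tolerance = 1e-12)
})

test_that("ensemble mean tracks the truth profile for noisy realisations", {
    truthFn <- function(x) 100 * (1 - 0.6 * exp(-x^2 / (2 * 4.5)))
    pos <- seq(-50, 50, by = 0.5)
    profs <- lapply(1:20, function(s) {
        set.seed(s)
        new("AboralProfile", positions = pos,
            intensity = truthFn(pos) + rnorm(length(pos), 0, 5),
            channel = "ColIV", roiLength = 100, lineWidth = 5)
    })
    ee <- ensembleProfiles(profs)
    se <- ee@sd / sqrt(20)
    # mean within 2 SE of truth almost everywhere (allow a small slack for
    # the discrete grid)
    frac <- mean(abs(ee@mean - truthFn(ee@positions)) <= 2 * se)
    expect_gt(frac, 0.90)
})

test_that("square-ROI means follow pixel-count weighting", {
    px <- matrix(2, 100, 100)
    px[, 51:100] <- 8          # right half bright (x >= 50.5 px -> 25 um)
    img <- CalibratedImage(px, 0.5)
    m <- roiMeanIntensity(img, rbind(c(10, 25), c(40, 25)), roiSide = 10)
    expect_equal(m, c(2, 8))
    # constant image: any ROI returns the constant
    cst <- CalibratedImage(matrix(5, 60, 60), 1)
    expect_equal(roiMeanIntensity(cst, cbind(30, 30), 10), 5)
    # ROI straddling the boundary: pixel-count weighted mixture
    straddle <- roiMeanIntensity(img, cbind(24.75, 25), roiSide = 10)
    expect_lt(abs(straddle - 5), 0.3)
    expect_error(roiMeanIntensity(img, cbind(2, 25), 10), "bounds")
})
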