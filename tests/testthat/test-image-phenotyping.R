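test_that("channel extraction matches the documented conventions", {
    rgb <- array(0, dim = c(4, 5, 3))
    rgb[, , 1] <- 10; rgb[, , 2] <- 20; rgb[, , 3] <- 200
    expect_true(all(extractChannel(rgb, "blue") == 200))
    rgb[, , 3] <- 30
    lum <- 0.299 * 10 + 0.587 * 20 + 0.114 * 30
    expect_equal(unique(as.vector(extractChannel(rgb, "gray"))), lum)
    gray <- matrix(42, 3, 3)
    expect_identical(extractChannel(gray, "gray"), gray)
    expect_identical(extractChannel(gray, "blue"), gray)
})

test_that("median-scaled threshold and strict binarization behave at boundaries", {
    r <- matrix(100, 10, 10)
    r[1, 1:3] <- c(250, 250, 250)
    expect_equal(medianThreshold(r, 1.7), 170)
    expect_equal(medianThreshold(r, 1.4), 140)
    const <- matrix(80, 5, 5)
    expect_equal(medianThreshold(const, 1.7), 136)
    expect_false(any(binarize(const, medianThreshold(const, 1.7))))
    expect_false(any(binarize(r, 255)))
    expect_true(all(binarize(r, 99)))
})

test_that("thresholding a rendered pouch recovers the truth mask exactly", {
    sp <- randomPouchSpec(seed = 21, nSpecks = 0)
    out <- renderPouchImage(sp)
    thr <- medianThreshold(out$raster, 1.7)
    expect_equal(binarize(out$raster, thr), out$truth$mask)
})

test_that("particle labeling agrees with a brute-force flood fill", {
    # two disjoint squares
    mask <- matrix(FALSE, 20, 20)
    mask[2:4, 2:4] <- TRUE
    mask[10:15, 10:14] <- TRUE
    ps <- labelParticles(mask, 8)
    expect_equal(nrow(ps$particles), 2)
    expect_equal(sort(ps$particles$n_px), c(9, 30))

    single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
    expect_equal(labelParticles(single, 4)$particles$n_px, 1)

    # diagonal chain: connected under 8, n singletons under 4
    diag10 <- diag(10) > 0
    expect_equal(nrow(labelParticles(diag10, 8)$particles), 1)
    expect_equal(nrow(labelParticles(diag10, 4)$particles), 10)

    set.seed(33)
    for (conn in c(4L, 8L)) for (rep in 1:6) {
        m <- matrix(runif(30 * 25) < 0.35, 30, 25)
        ours <- labelParticles(m, conn)$labels
        oracle <- bruteFloodFill(m, conn)
        expect_identical(ours, oracle)
    }
})

test_that("noise removal keeps exactly the particles above the size cutoff", {
    mask <- matrix(FALSE, 9, 320)
    mask[1, 1:50] <- TRUE     # 50 px
    mask[3, 1:299] <- TRUE    # 299 px
    mask[5, 1:300] <- TRUE    # 300 px
    mask[7, 1:301] <- TRUE    # 301 px
    ps <- removeNoise(labelParticles(mask, 8), 300)
    expect_equal(ps$particles$n_px, 301)
    expect_equal(nrow(attr(ps, "removalLog")), 3)

    none <- removeNoise(labelParticles(matrix(FALSE, 5, 5), 8), 300)
    expect_equal(nrow(none$particles), 0)

    sp <- randomPouchSpec(seed = 5, nRoots = 1, nShoots = 0, nSpecks = 8)
    out <- renderPouchImage(sp)
    seg <- removeNoise(labelParticles(binarize(out$raster, 170), 8), 300)
    expect_equal(sum(seg$particles$n_px), out$truth$areaPx)
})

test_that("areas convert exactly through the calibration and obey the scale law", {
    mask <- matrix(FALSE, 60, 60)
    mask[1:45, 1:50] <- TRUE    # 2250 px
    ps <- labelParticles(mask, 8)
    expect_equal(totalArea(ps, calibrationFor("taipei")), 10)
    expect_equal(totalArea(labelParticles(matrix(FALSE, 4, 4), 8),
                           calibrationFor("taipei")), 0)
    c1 <- calibration(100, 10)
    c2 <- calibration(200, 10)
    expect_equal(totalArea(ps, c2), totalArea(ps, c1) / 4)
})

test_that("segmented area is invariant under translation and rotation", {
    sp <- randomPouchSpec(seed = 42, nSpecks = 0)
    out <- renderPouchImage(sp)
    mask <- out$truth$mask
    area <- function(m) sum(labelParticles(m, 8)$particles$n_px)
    shifted <- matrix(FALSE, nrow(mask) + 5, ncol(mask) + 5)
    shifted[6:(nrow(mask) + 5), 6:(ncol(mask) + 5)] <- mask
    expect_equal(area(shifted), area(mask))
    rotated <- t(mask)[ncol(mask):1, ]
    expect_equal(area(rotated), area(mask))
})

test_that("Feret diameter equals the quadratic-time oracle", {
    bar <- cbind(x = 0:99, y = rep(0, 100))
    expect_equal(feretDiameter(bar), 99)
    cal <- calibration(450, 30)
    expect_equal(feretDiameter(bar, cal), 99 / 15)
    expect_equal(feretDiameter(cbind(x = 5, y = 7)), 0)
    expect_error(feretDiameter(cbind(x = numeric(0), y = numeric(0))),
                 "empty")

    set.seed(44)
    for (rep in 1:25) {
        n <- sample(2:60, 1)
        coords <- unique(cbind(x = sample(0:30, n, TRUE),
                               y = sample(0:30, n, TRUE)))
        expect_equal(feretDiameter(coords), bruteFeretPx(coords))
    }
})

test_that("the pouch pipeline measures rendered structures to their truth", {
    cal <- calibrationFor("taipei")
    sp <- randomPouchSpec(seed = 13)
    out <- renderPouchImage(sp)
    meas <- phenotypePouch(out$raster, shootConfig = NULL, cal = cal,
                           metadata = list(line = "L1", day = 4))
    expect_equal(meas$root_area_mm2 / mm2PerPx(cal), out$truth$areaPx)

    # a lone upright shoot: Feret length within 1 px of its vertical extent
    shootSpec <- imageSpec(100, 120, shoots = list(
        list(base = c(50, 110), length = 90, width = 8, gray = 200)))
    shootOut <- renderPouchImage(shootSpec)
    m2 <- phenotypePouch(shootOut$raster, rootConfig = NULL, cal = cal)
    expect_equal(m2$n_shoots, 1)
    expect_lt(abs(attr(m2, "shootLengthsMm") * pxPerMm(cal) - 90), 1)

    blank <- matrix(100, 50, 50)
    m3 <- phenotypePouch(blank, cal = cal)
    expect_equal(m3$root_area_mm2, 0)
    expect_equal(m3$n_shoots, 0)

    expect_error(phenotypePouch(blank), "Calibration")
})

test_that("pouch images survive a PNG round trip", {
    sp <- randomPouchSpec(seed = 2)
    out <- renderPouchImage(sp)
    path <- withr::local_tempfile(fileext = ".png")
    writePouchImage(out$raster, path)
    back <- readPouchImage(path)
    expect_equal(back, out$raster, tolerance = 1e-6, ignore_attr = TRUE)
    meas <- phenotypePouch(path, shootConfig = NULL,
                           cal = calibrationFor("taipei"))
    expect_equal(meas$root_area_mm2 / mm2PerPx(calibrationFor("taipei")),
                 out$truth$areaPx)
})
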