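# Image IO, colour calibration, intensity conversion, surface detection,
# ROI construction and mean intensity.

test_that("PNG round trip is pixel identical and sidecar metadata loads", {
  g <- generateProfileImage(smallScenario(textureSd = 5, seed = 2), "img1")
  p <- withr::local_tempfile(fileext = ".png")
  writeProfileImage(g$image, p, sidecar = list(lon = 175.167, lat = -36.801,
                                               timestamp = "2013-04-02"))
  back <- readProfileImage(p)
  expect_identical(imagePixels(back), imagePixels(g$image))
  expect_identical(imageId(back), "img1")
  expect_equal(back@position, c(175.167, -36.801))
})

test_that("single-channel images are rejected with a channel-count error", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(100), 10, 10), p)
  expect_error(readProfileImage(p), "channel")
})

test_that("16-bit TIFFs are rescaled to 0-255 by value/257", {
  set.seed(6)
  # stored 16-bit values 257*k divide exactly: the read-back must be k
  k <- array(sample(0:255, 60 * 50 * 3, replace = TRUE), c(60, 50, 3))
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(k / 255, p, bits.per.sample = 16)
  expect_message(img <- readProfileImage(p), "16-bit")
  expect_equal(imagePixels(img), k, ignore_attr = TRUE)
  # arbitrary 16-bit values agree with the value/257 oracle to 1 grey
  arr <- array(runif(30 * 20 * 3), c(30, 20, 3))
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(arr, p2, bits.per.sample = 16)
  suppressMessages(img2 <- readProfileImage(p2))
  oracle <- round(round(arr * 65535) / 257)
  expect_lte(max(abs(imagePixels(img2) - oracle)), 1)
})

test_that("HSI intensity is the channel mean on the 0-255 scale", {
  expect_equal(rgbToIntensity(array(c(61, 61, 61), c(1, 1, 3)))[1, 1], 61)
  expect_equal(rgbToIntensity(array(c(255, 0, 0), c(1, 1, 3)))[1, 1], 85)
  uni <- array(93, c(5, 4, 3))
  expect_true(all(rgbToIntensity(uni) == 93))
  # real-valued, not re-quantised
  expect_equal(rgbToIntensity(array(c(1, 0, 0), c(1, 1, 3)))[1, 1], 1 / 3)
})

test_that("calibration is near-identity on an undistorted image", {
  g <- generateProfileImage(smallScenario())
  cal <- calibrateColours(g$image)
  k <- calibrationCoefficients(cal)
  expect_true(all(abs(k[, "gain"] - 1) < 1e-6))
  expect_true(all(abs(k[, "offset"]) < 1e-6))
})

test_that("calibration inverts a known affine distortion within 1 grey", {
  for (seed in 1:5) {
    set.seed(seed)
    dist <- cbind(runif(3, 0.85, 1.25), runif(3, -15, 15))
    g <- generateProfileImage(smallScenario(distortion = dist, seed = seed))
    cal <- calibrateColours(g$image)
    measured <- spiFootprint:::.measureSwatches(
      imagePixels(cal), stripLocation(150, 120))
    ref <- spiStripReference()
    # oracle: invert the known affine on the stored 8-bit swatches;
    # compare only swatches the distortion did not saturate
    rawRef <- sweep(sweep(ref, 2, dist[, 1], `*`), 2, dist[, 2], `+`)
    stored <- round(pmin(pmax(rawRef, 0), 255))
    oracle <- sweep(sweep(stored, 2, dist[, 2], `-`), 2, dist[, 1], `/`)
    ok <- rawRef > 1 & rawRef < 254
    expect_true(all(abs(measured[ok] - oracle[ok]) < 1))
  }
})

test_that("degenerate strips raise calibration errors", {
  g <- generateProfileImage(smallScenario(
    distortion = cbind(c(1e-9, 1, 1), c(100, 0, 0))))
  expect_error(calibrateColours(g$image), "calibration failure")
})

test_that("calibration is idempotent within tolerance", {
  dist <- cbind(c(1.15, 0.9, 1.05), c(-8, 6, 2))
  g <- generateProfileImage(smallScenario(distortion = dist))
  once <- calibrateColours(g$image)
  twice <- calibrateColours(once)
  k <- calibrationCoefficients(twice)
  expect_true(all(abs(k[, "gain"] - 1) < 0.02))
  expect_true(all(abs(k[, "offset"]) < 1.5))
})

test_that("surface detection matches generator truth within 3 px", {
  flat <- generateProfileImage(smallScenario(textureSd = 5, seed = 3))
  If <- rgbToIntensity(flat$image)
  sf <- detectSurface(If, columns = flat$truth$analysisCols)
  expect_true(all(abs(sf - flat$truth$surfaceRows) <= 3))
  slop <- generateProfileImage(smallScenario(sloped = TRUE, textureSd = 5,
                                             seed = 4))
  Is <- rgbToIntensity(slop$image)
  ss <- detectSurface(Is, columns = slop$truth$analysisCols)
  expect_true(all(abs(ss - slop$truth$surfaceRows) <= 3))
})

test_that("uniform images give a detection-failure error", {
  expect_error(detectSurface(matrix(120, 80, 60)), "detection failure")
})

test_that("manual contours override detection", {
  manual <- rep(33, 60)
  expect_identical(detectSurface(matrix(120, 80, 60), contour = manual),
                   manual)
})

test_that("mm offsets convert to the documented pixel counts", {
  # 0.08 mm/px: 10 mm -> 125 px, 40 mm -> 500 px
  roi <- makeRoi(rep(10, 4), "polygon", topOffsetMm = 10, extentMm = 40,
                 mmPerPx = 0.08, imageRows = 700)
  v <- roiVertices(roi)
  expect_equal(min(v[, 2]), 10 + 125 - 0.5)
  expect_equal(max(v[, 2]), 10 + 125 + 500 - 1 + 0.5)
  m <- meanIntensity(matrix(50, 700, 4), roi)
  expect_identical(m$pixel_count, 4L * 500L)
})

test_that("flat surfaces make polygon and rectangle ROIs identical", {
  I <- matrix(runif(200 * 30, 0, 255), 200, 30)
  srf <- rep(40, 30)
  mp <- meanIntensity(I, makeRoi(srf, "polygon", 1, 8, 0.08, 200))
  mr <- meanIntensity(I, makeRoi(srf, "rectangle", 1, 8, 0.08, 200))
  expect_equal(mp$mean_grey, mr$mean_grey)
  expect_identical(mp$pixel_count, mr$pixel_count)
})

test_that("deepest-anchored rectangles lose pixels on sloped surfaces", {
  srf <- round(seq(40, 90, length.out = 30))
  I <- matrix(runif(220 * 30, 0, 255), 220, 30)
  # both bands reach the image bottom; the contour-following polygon is
  # clipped only in its deepest columns, the deepest-anchored rectangle
  # in every column, so the polygon keeps more pixels
  expect_warning(
    rp <- makeRoi(srf, "polygon", 1, 10, 0.08, 220, clip = TRUE),
    "clipped")
  expect_warning(
    rr <- makeRoi(srf, "rectangle", 1, 10, 0.08, 220, clip = TRUE),
    "clipped")
  expect_gt(meanIntensity(I, rp)$pixel_count,
            meanIntensity(I, rr)$pixel_count)
  expect_error(makeRoi(srf, "rectangle", 1, 10, 0.08, 220), "mm")
})

test_that("mean intensity matches direct expectations", {
  uni <- matrix(61, 80, 40)
  roi <- makeRoi(rep(10, 40), "polygon", 1, 2, 0.08, 80)
  expect_equal(meanIntensity(uni, roi)$mean_grey, 61)
  # checkerboard over an even pixel count averages to 127.5
  cb <- 255 * outer(1:80, 1:40, function(r, c) (r + c) %% 2)
  expect_equal(meanIntensity(cb, roi)$mean_grey, 127.5)
})

test_that("ROI means equal the naive per-pixel loop oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    I <- matrix(runif(150 * 40, 0, 255), 150, 40)
    srf <- round(seq(20, 20 + seed * 8, length.out = 40))
    attr(srf, "columns") <- 1:40
    roi <- makeRoi(srf, "polygon", 1, 4, 0.08, 150)
    got <- meanIntensity(I, roi)
    ora <- naiveRoiMean(I, roi)
    expect_identical(got$pixel_count, ora$count)
    expect_lt(abs(got$mean_grey - ora$mean), 1e-9)
  }
})

test_that("mean intensity is invariant under transposition and translation", {
  set.seed(7)
  I <- matrix(runif(120 * 50, 0, 255), 120, 50)
  srf <- round(seq(25, 45, length.out = 50))
  roi <- makeRoi(srf, "polygon", 1, 3, 0.08, 120)
  base <- meanIntensity(I, roi)
  # transpose: swap (col, row) in both image and ROI
  v <- roiVertices(roi)
  roiT <- new("RegionOfInterest", mode = "polygon",
              vertices = v[, c(2, 1)])
  expect_equal(meanIntensity(t(I), roiT)$mean_grey, base$mean_grey)
  # translate by (dr, dc) inside a larger canvas
  big <- matrix(0, 160, 90)
  big[31:150, 21:70] <- I
  roiS <- new("RegionOfInterest", mode = "polygon",
              vertices = cbind(v[, 1] + 20, v[, 2] + 30))
  expect_equal(meanIntensity(big, roiS)$mean_grey, base$mean_grey)
})

test_that("rectangle and polygon means are indistinguishable on
           homogeneous sediment (paired design)", {
  n <- 175
  pg <- rg <- numeric(n)
  for (i in seq_len(n)) {
    g <- generateProfileImage(
      smallScenario(targetGrey = 80, sloped = TRUE, textureSd = 5,
                    seed = 1000 + i, size = c(150, 100)))
    I <- rgbToIntensity(g$image)
    srf <- detectSurface(I, columns = g$truth$analysisCols)
    pg[i] <- meanIntensity(I, makeRoi(srf, "polygon", 1, 2, 0.08,
                                      150))$mean_grey
    rg[i] <- meanIntensity(I, makeRoi(srf, "rectangle", 1, 2, 0.08,
                                      150))$mean_grey
  }
  res <- pairedT(pg, rg)
  expect_identical(res$df, n - 1)
  expect_gt(res$p, 0.05)
})
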