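test_that("channel extraction returns the requested plane", {
  r <- Raster(matrix(5, 4, 4))
  expect_identical(toGrayscale(r, "red"), r)      # grayscale: identity
  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 7; rgb[, , 3] <- 9
  expect_true(all(pixelData(toGrayscale(rgb, "red")) == 7))
  rgb2 <- array(round(runif(12, 0, 255)), c(2, 2, 3))
  expect_equal(pixelData(toGrayscale(rgb2, "blue")), rgb2[, , 3],
               ignore_attr = TRUE)
  lum <- toGrayscale(rgb2, "luminance")
  expect_equal(pixelData(lum),
               0.299 * rgb2[, , 1] + 0.587 * rgb2[, , 2] +
                 0.114 * rgb2[, , 3], ignore_attr = TRUE)
  expect_error(toGrayscale(rgb2, "alpha"))
  expect_error(toGrayscale(array(0, c(2, 2, 2))), "channels")
})

test_that("background subtraction removes smooth structure, keeps objects", {
  expect_true(all(pixelData(subtractBackground(
    Raster(matrix(50, 30, 30)), 10)) == 0))
  # bright disk of radius 5 on flat 50, ball radius 40
  img <- matrix(50, 96, 96) + 100 * diskMatrix(96, 96, 48, 48, 5)
  out <- pixelData(subtractBackground(Raster(img), 40))
  expect_lt(max(out[diskMatrix(96, 96, 48, 48, 8) == 0]), 1)  # bg ~ 0
  expect_gt(out[48, 48], 95)                 # amplitude within 5%
  # gentle linear gradient removed
  grad <- outer(seq(0, 20, length = 96), seq(0, 10, length = 96), `+`) + 60
  img2 <- grad + 100 * diskMatrix(96, 96, 48, 48, 5)
  out2 <- pixelData(subtractBackground(Raster(img2), 40))
  expect_lt(max(out2[diskMatrix(96, 96, 48, 48, 8) == 0]), 10)
  expect_gt(out2[48, 48], 90)
  expect_error(subtractBackground(Raster(img), 0), "radius")
})

test_that("light-background subtraction inverts before opening", {
  # dark disk on light background comes out bright on ~zero background
  img <- matrix(200, 64, 64) - 80 * diskMatrix(64, 64, 32, 32, 5)
  out <- pixelData(subtractBackground(Raster(img), 30,
                                      lightBackground = TRUE))
  expect_gt(out[32, 32], 75)
  expect_lt(max(out[diskMatrix(64, 64, 32, 32, 9) == 0]), 1)
})

test_that("sharpen is the normalized 3x3 high-boost kernel", {
  expect_true(all(pixelData(sharpenImage(Raster(matrix(7, 8, 8)))) == 7))
  imp <- matrix(0, 9, 9); imp[5, 5] <- 4
  out <- pixelData(sharpenImage(Raster(imp)))
  expect_equal(out[5, 5], 12)
  expect_true(all(out[4:6, 4:6][-5] == 0))   # -1 clipped to depth range
  # step edge: overshoot bright side, undershoot dark side
  step <- matrix(rep(c(40, 120), each = 50), 10, 10)
  s <- pixelData(sharpenImage(Raster(step)))
  expect_gt(max(s[, 6]), 120)
  expect_lt(min(s[, 5]), 40)
})

test_that("contrast enhancement maps saturation quantiles to the range", {
  full <- Raster(matrix(seq(0, 255, length = 100), 10, 10))
  expect_equal(pixelData(enhanceContrast(full, 0)), pixelData(full),
               tolerance = 1e-12)
  two <- Raster(matrix(rep(c(10, 200), 50), 10, 10))
  e <- pixelData(enhanceContrast(two, 0))
  expect_setequal(unique(as.vector(e)), c(0, 255))
  # 1000 pixels, 2 extreme bright outliers, fraction 0.004
  set.seed(4)
  v <- runif(998, 40, 60)
  m <- matrix(c(v, 250, 251), 25, 40)
  out <- pixelData(enhanceContrast(Raster(m), 0.004))
  expect_true(all(out[m >= 250] == 255))     # outliers saturated
  expect_lte(sum(out == 255), 3)             # only the top quantile pinned
  expect_gt(diff(range(out[m <= 60])), 250)  # rest stretched to depth
  expect_error(enhanceContrast(full, 0.6), "0.5")
  expect_error(enhanceContrast(full, -0.1), "0.5")
})

test_that("sobel magnitude matches the convolution oracle", {
  expect_true(all(pixelData(sobelEdges(Raster(matrix(9, 8, 8)))) == 0))
  h <- 13
  step <- matrix(rep(c(0, h), each = 60), 12, 10)
  s <- pixelData(sobelEdges(Raster(step)))
  expect_equal(max(s[3:10, ]), 4 * h)        # maximal response 4h
  # rotation symmetry of the magnitude
  set.seed(11)
  m <- matrix(runif(144, 0, 255), 12, 12)
  r1 <- pixelData(sobelEdges(Raster(m)))
  rot <- t(m)[ncol(m):1, ]                   # 90 degree rotation
  r2 <- pixelData(sobelEdges(Raster(rot)))
  expect_equal(r2, t(r1)[ncol(r1):1, ], tolerance = 1e-9)
})

test_that("gaussian blur is a normalized truncated kernel", {
  expect_true(all(abs(pixelData(gaussianBlur(Raster(matrix(5, 9, 9)), 1.3))
                      - 5) < 1e-9))
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  out <- pixelData(gaussianBlur(Raster(imp), 2))
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_equal(which.max(out), 16 + 15 * 31)
  # central value equals the dense normalized 2-D gaussian
  r <- ceiling(3 * 2)
  k2 <- outer(exp(-(-r:r)^2 / 8), exp(-(-r:r)^2 / 8))
  k2 <- k2 / sum(k2)
  expect_equal(out[16, 16], k2[r + 1, r + 1], tolerance = 1e-12)
  expect_error(gaussianBlur(Raster(imp), 0), "sigma")
})

test_that("blurring a binary mask suppresses speckle, keeps solid shapes", {
  m <- matrix(0, 24, 24)
  m[4, 4] <- 1                       # isolated speck
  m[10:16, 6:20] <- 1                # solid bar
  out <- pixelData(gaussianBlur(BinaryMask(m), 2))
  expect_equal(out[4, 4], 0)
  expect_equal(out[13, 13], 1)
  expect_s4_class(gaussianBlur(BinaryMask(m), 2), "BinaryMask")
})

test_that("IsoData binarization converges to the intermeans fixpoint", {
  expect_true(all(pixelData(makeBinary(Raster(matrix(9, 6, 6)))) == 0))
  bi <- Raster(matrix(rep(c(10, 200), each = 50), 10, 10))
  expect_equal(isodataThreshold(pixelData(bi)), 105)
  mask <- makeBinary(bi)
  expect_equal(sum(pixelData(mask)), 50)
  expect_true(all(pixelData(mask)[pixelData(bi) == 200] == 1))
  # partition property on random data, and agreement with direct iteration
  set.seed(21)
  for (i in 1:10) {
    r <- randRaster(12, 12)
    t <- isodataThreshold(pixelData(r))
    expect_equal(t, oracle_isodata(pixelData(r)))
    mk <- pixelData(makeBinary(r))
    expect_true(all((mk == 1) == (pixelData(r) > t)))
  }
})

test_that("alternative threshold methods are available", {
  set.seed(3)
  r <- Raster(matrix(c(runif(170, 0, 30), runif(30, 150, 255)), 10, 20))
  mo <- makeBinary(r, method = "otsu")
  mt <- makeBinary(r, method = "triangle")
  expect_true(all(pixelData(mo)[pixelData(r) > 150] == 1))
  expect_true(all(pixelData(mt)[pixelData(r) > 150] == 1))
  # triangle keys off the background peak: threshold below intermeans
  skewed <- c(rep(2, 960), runif(30, 35, 90), runif(10, 150, 255))
  expect_lt(triangleThreshold(skewed), isodataThreshold(skewed))
})

test_that("closing bridges gaps and is extensive", {
  disk <- BinaryMask(diskMatrix(20, 20, 10, 10, 6))
  expect_equal(pixelData(closeMask(disk)), pixelData(disk))
  # circle outline with a 1-pixel gap becomes a closed ring
  th <- seq(0, 2 * pi, length = 200)
  ring <- matrix(0, 24, 24)
  ring[cbind(round(12 + 8 * sin(th)), round(12 + 8 * cos(th)))] <- 1
  ring[12, 20] <- 0                  # knock out one boundary pixel
  closed <- closeMask(BinaryMask(ring))
  filled <- fillHoles(closed)
  expect_gt(sum(pixelData(filled)), pi * 6^2)   # interior captured
  empty <- BinaryMask(matrix(0, 8, 8))
  expect_equal(sum(pixelData(closeMask(empty))), 0)
  set.seed(31)
  for (i in 1:20) {
    m <- randMask(10, 10, 0.3)
    out <- closeMask(m)
    expect_true(all(pixelData(out) >= pixelData(m)))   # extensive
    # matches the exhaustive 3x3 dilate/erode oracle
    expect_equal(pixelData(out),
                 pmax(oracle_morph3x3(oracle_morph3x3(pixelData(m), "max"),
                                      "min"), pixelData(m)))
  }
})

test_that("hole filling follows border connectivity and is idempotent", {
  ring <- matrix(0, 9, 9)
  ring[3:7, 3] <- 1; ring[3:7, 7] <- 1; ring[3, 3:7] <- 1; ring[7, 3:7] <- 1
  expect_equal(sum(pixelData(fillHoles(BinaryMask(ring)))), 25)
  cshape <- matrix(0, 9, 9)
  cshape[2:8, 2] <- 1; cshape[2, 2:7] <- 1; cshape[8, 2:7] <- 1
  expect_equal(pixelData(fillHoles(BinaryMask(cshape))), cshape)
  full <- BinaryMask(matrix(1, 5, 5))
  expect_equal(pixelData(fillHoles(full)), matrix(1, 5, 5))
  set.seed(41)
  for (i in 1:25) {
    m <- randMask(12, 12, 0.45)
    f1 <- fillHoles(m)
    expect_equal(pixelData(f1), oracle_fill(pixelData(m)))
    expect_equal(pixelData(fillHoles(f1)), pixelData(f1))  # idempotent
  }
})

test_that("rank filters implement digital-disk dilation and erosion", {
  single <- matrix(0, 15, 15); single[8, 8] <- 1
  out <- pixelData(rankFilter(BinaryMask(single), 3, "maximum"))
  off <- diskOffsets(3)
  expected <- matrix(0, 15, 15)
  expected[cbind(8 + off$dy, 8 + off$dx)] <- 1
  expect_equal(out, expected)                 # digital disk by definition
  disk <- BinaryMask(diskMatrix(40, 40, 20, 20, 12))
  rec <- rankFilter(rankFilter(disk, 3, "maximum"), 3, "minimum")
  expect_equal(pixelData(rec), pixelData(disk))  # opening recovers disk
  thin <- matrix(0, 12, 12); thin[6, 3:10] <- 1
  expect_equal(sum(pixelData(rankFilter(BinaryMask(thin), 2, "minimum"))), 0)
  expect_error(rankFilter(disk, 0.5, "maximum"), "radius")
})

test_that("outlier removal replaces median-deviating pixels only", {
  lone <- matrix(0, 11, 11); lone[6, 6] <- 1
  expect_equal(sum(pixelData(removeOutliers(BinaryMask(lone), 2))), 0)
  block <- matrix(0, 15, 15); block[4:12, 4:12] <- 1
  out <- removeOutliers(BinaryMask(block), 2)
  expect_equal(pixelData(out)[5:11, 5:11], block[5:11, 5:11])
  dark <- removeOutliers(BinaryMask(lone), 2, polarity = "dark")
  expect_equal(pixelData(dark), lone)         # bright speck untouched
  expect_error(removeOutliers(BinaryMask(lone), 2, threshold = -1))
})

test_that("all window filters agree exactly with exhaustive oracles", {
  # the primitive-oracle suite: random small rasters vs naive
  # brute-force implementations, exact equality
  set.seed(100)
  for (i in 1:25) {
    r <- randRaster(14, 14)
    p <- pixelData(r)
    expect_equal(pixelData(sharpenImage(r)),
                 pmin(pmax(oracle_conv2(p, matrix(c(-1, -1, -1, -1, 12,
                   -1, -1, -1, -1), 3, 3) / 4), 0), 255), tolerance = 1e-12)
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    expect_equal(pixelData(sobelEdges(r)),
                 sqrt(oracle_conv2(p, kx)^2 + oracle_conv2(p, t(kx))^2),
                 tolerance = 1e-9)
    rad <- sample(c(1, 2, 3), 1)
    expect_equal(pixelData(rankFilter(r, rad, "maximum")),
                 oracle_rank(p, rad, "max"))
    expect_equal(pixelData(rankFilter(r, rad, "minimum")),
                 oracle_rank(p, rad, "min"))
    thr <- sample(c(10, 40, 80), 1)
    pol <- sample(c("bright", "dark"), 1)
    expect_equal(pixelData(removeOutliers(r, rad, thr, pol)),
                 oracle_remove_outliers(p, rad, thr, pol == "bright"))
    br <- sample(c(2, 3, 4), 1)
    expect_equal(pixelData(subtractBackground(r, br)),
                 pmax(p - oracle_ball_open(p, br), 0), tolerance = 1e-9)
  }
  # gaussian blur vs dense 2-D kernel convolution oracle
  set.seed(101)
  for (i in 1:5) {
    r <- randRaster(12, 12)
    sg <- c(0.8, 1.5, 2)[(i %% 3) + 1]
    n <- ceiling(3 * sg)
    k1 <- exp(-(-n:n)^2 / (2 * sg^2)); k1 <- k1 / sum(k1)
    expect_equal(pixelData(gaussianBlur(r, sg)),
                 oracle_conv2(pixelData(r), outer(k1, k1)),
                 tolerance = 1e-9)
  }
})

test_that("image operations preserve dimensions and calibration", {
  r <- Raster(matrix(runif(120, 0, 255), 10, 12), calibration = 1.7)
  for (f in list(function(x) subtractBackground(x, 3), sharpenImage,
                 function(x) enhanceContrast(x, 0.01), sobelEdges,
                 function(x) gaussianBlur(x, 1),
                 function(x) rankFilter(x, 2, "minimum"),
                 function(x) removeOutliers(x, 2, 30))) {
    out <- f(r)
    expect_identical(dim(out), dim(r))
    expect_equal(calibration(out), 1.7)
  }
  expect_equal(calibration(makeBinary(r)), 1.7)
})
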