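test_that("measurement basics: area, perimeter, centroid, intensity", {
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  rec <- measureParticles(labelComponents(BinaryMask(single, 2)))
  expect_equal(rec$area, 4)                    # 1 px at 2 um/px
  expect_equal(rec$perimeter, 0)
  expect_equal(rec$circularity, 1)
  expect_equal(c(rec$x, rec$y), c(3, 3))

  block <- matrix(0, 14, 14); block[3:12, 3:12] <- 1
  rec2 <- measureParticles(labelComponents(BinaryMask(block)))
  expect_equal(rec2$area, 100)
  expect_equal(rec2$perimeter, 36)             # chain code of 10x10 square
  expect_equal(unlist(rec2[c("bbox_x0", "bbox_y0", "bbox_w", "bbox_h")]),
               c(3, 3, 10, 10), ignore_attr = TRUE)
  expect_false(rec2$touches_edge)

  lab <- labelComponents(BinaryMask(block))
  rec3 <- measureParticles(lab, redirect = Raster(matrix(7, 14, 14)))
  expect_equal(rec3$mean_intensity, 7)
  expect_equal(rec3$integrated_intensity, 700)
  expect_error(measureParticles(lab, redirect = Raster(matrix(7, 5, 5))),
               "dimensions")
})

test_that("chain-code perimeters match hand-traced contours", {
  shapes <- list(
    # rectangle h x w: 2(h-1) + 2(w-1)
    list(fun = function() { m <- matrix(0, 10, 12); m[3:7, 2:9] <- 1; m },
         per = 2 * 4 + 2 * 7),
    # domino: two orthogonal steps
    list(fun = function() { m <- matrix(0, 4, 4); m[2, 2:3] <- 1; m },
         per = 2),
    # diagonal bar of k pixels: 2 (k-1) sqrt(2)
    list(fun = function() { m <- matrix(0, 8, 8); m[cbind(2:6, 2:6)] <- 1; m },
         per = 2 * 4 * sqrt(2)),
    # plus sign: hand-traced 8 orthogonal + 4 diagonal steps
    list(fun = function() { m <- matrix(0, 7, 7)
                            m[4, 2:6] <- 1; m[2:6, 4] <- 1; m },
         per = 8 + 4 * sqrt(2)))
  for (s in shapes) {
    rec <- measureParticles(labelComponents(BinaryMask(s$fun())))
    expect_equal(rec$perimeter, s$per, tolerance = 1e-9)
  }
})

test_that("circularity separates disks from elongated shapes", {
  # chain-code perimeters overestimate smooth contours by ~5%, so the
  # circularity of large digital disks plateaus near 0.9 (it cannot reach
  # 1 under this perimeter definition); it must stay high and stable
  circ <- vapply(seq(5, 50, by = 5), function(r) {
    m <- diskMatrix(2 * r + 9, 2 * r + 9, r + 5, r + 5, r)
    measureParticles(labelComponents(BinaryMask(m)))$circularity
  }, 1)
  expect_true(all(circ >= 0.85))
  expect_true(all(circ <= 1))
  expect_lt(max(abs(diff(circ))), 0.05)       # stable across radii
  bars <- vapply(c(3, 8, 16, 30), function(k) {
    m <- matrix(0, 6, k + 4); m[3, 3:(k + 2)] <- 1
    measureParticles(labelComponents(BinaryMask(m)))$circularity
  }, 1)
  expect_true(all(diff(bars) < 0))            # falls with elongation
  expect_lt(bars[4], min(circ))               # disks >> bars
})

test_that("filtering is a pure subset under the stated predicate", {
  lab <- labelComponents(BinaryMask(diskMatrix(20, 20, 10, 10, 5)))
  rec <- measureParticles(lab)
  expect_identical(filterParticles(rec, particleFilter()), rec)  # identity
  two <- data.frame(id = 1:2, area = c(40, 60), perimeter = c(20, 25),
                    circularity = c(0.9, 0.8), x = 1:2, y = 1:2,
                    touches_edge = c(FALSE, TRUE))
  kept <- filterParticles(two, particleFilter(minSize = 50))
  expect_equal(kept$id, 2)
  set.seed(7)
  recs <- data.frame(id = 1:50, area = runif(50, 0, 200),
                     circularity = runif(50), touches_edge = runif(50) > .5)
  f <- particleFilter(30, 150, 0.2, 0.9, excludeEdges = TRUE)
  kept2 <- filterParticles(recs, f)
  manual <- recs[recs$area >= 30 & recs$area <= 150 &
                 recs$circularity >= 0.2 & recs$circularity <= 0.9 &
                 !recs$touches_edge, ]
  expect_identical(kept2, manual)             # bit-identical survivors
  expect_error(particleFilter(minSize = 10, maxSize = 5))
  expect_error(particleFilter(minCircularity = 0.8, maxCircularity = 0.2))
})

test_that("summaries agree with a sorting-based oracle", {
  one <- data.frame(area = 5, perimeter = 9)
  s1 <- summarizeParticles(one)
  expect_equal(c(s1$n, s1$mean_area), c(1, 5))
  four <- data.frame(area = 1:4, perimeter = c(2, 4, 6, 8))
  s4 <- summarizeParticles(four)
  expect_equal(c(s4$mean_area, s4$median_area), c(2.5, 2.5))
  empty <- summarizeParticles(four[0, ])
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_area))
  set.seed(17)
  rnd <- data.frame(area = runif(100, 1, 500), perimeter = runif(100, 1, 90))
  s <- summarizeParticles(rnd)
  v <- sort(rnd$area)
  qidx <- function(p) { h <- (100 - 1) * p + 1
    v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)]) }
  expect_equal(s$mean_area, mean(rnd$area))
  expect_equal(s$median_area, qidx(0.5))
  expect_equal(s$q25_area, qidx(0.25))
  expect_equal(s$q75_area, qidx(0.75))
})

test_that("calibration scales area quadratically, perimeter linearly", {
  m <- diskMatrix(30, 30, 15, 15, 8)
  r1 <- measureParticles(labelComponents(BinaryMask(m, calibration = 1)))
  r3 <- measureParticles(labelComponents(BinaryMask(m, calibration = 3)))
  expect_equal(r3$area, 9 * r1$area)
  expect_equal(r3$perimeter, 3 * r1$perimeter)
  expect_equal(r3$circularity, r1$circularity)  # dimensionless
})

test_that("edge contact is flagged and CSV export keeps the layout", {
  m <- matrix(0, 8, 8); m[1:3, 4:6] <- 1
  rec <- measureParticles(labelComponents(BinaryMask(m)))
  expect_true(rec$touches_edge)
  f <- tempfile(fileext = ".csv")
  writeParticles(rec, f, image = "scene.tif")
  back <- read.csv(f)
  expect_identical(names(back)[1:5],
                   c("image", "id", "area", "perimeter", "circularity"))
  expect_equal(back$area, rec$area)
})

test_that("particle measurements match direct aggregation on random labels", {
  set.seed(27)
  for (i in 1:15) {
    m <- randMask(15, 15, 0.4)
    lab <- labelComponents(m)
    if (nObjects(lab) == 0) next
    rec <- measureParticles(lab, redirect = randRaster(15, 15))
    p <- pixelData(lab)
    for (l in seq_len(nObjects(lab))) {
      idx <- which(p == l, arr.ind = TRUE)
      expect_equal(rec$area[l], nrow(idx))
      expect_equal(rec$x[l], mean(idx[, 2]))
      expect_equal(rec$y[l], mean(idx[, 1]))
      expect_equal(rec$bbox_w[l], diff(range(idx[, 2])) + 1)
      expect_equal(rec$touches_edge[l],
                   any(idx == 1 | idx[, 1] == 15 | idx[, 2] == 15))
    }
  }
})
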