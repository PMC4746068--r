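test_that("identical detection and reference sets pair exactly", {
  ref <- data.frame(id = 1:5, x = c(10, 30, 50, 70, 90), y = 20,
                    area = c(100, 200, 150, 80, 120))
  m <- matchObjects(ref, ref, maxCentroidDistance = 5)
  expect_equal(nrow(m$pairs), 5)
  expect_length(m$extra_detected, 0)
  expect_length(m$undetected_reference, 0)
  expect_equal(m$pairs$ref_id, m$pairs$det_id)
})

test_that("split rule: largest fragment matches, the rest become extras", {
  ref <- data.frame(id = 1, x = 10, y = 10, area = 100)
  det <- data.frame(id = 1:2, x = c(10, 12), y = c(10, 9),
                    area = c(70, 30))
  m <- matchObjects(det, ref, maxCentroidDistance = 10)
  expect_equal(m$pairs$det_id, 1)              # the 70-area fragment
  expect_equal(m$pairs$det_area, 70)
  expect_equal(m$extra_detected, 2)
  expect_equal(m$extra_assigned_ids, 2)        # numbered after last ref id
})

test_that("merge rule: one detection pairs with the larger reference", {
  ref <- data.frame(id = 1:2, x = c(10, 16), y = 10, area = c(100, 40))
  det <- data.frame(id = 1, x = 12, y = 10, area = 130)
  m <- matchObjects(det, ref, maxCentroidDistance = 10)
  expect_equal(m$pairs$ref_id, 1)              # the area-100 reference
  expect_equal(m$undetected_reference, 2)
  expect_length(m$extra_detected, 0)
})

test_that("matching conserves objects", {
  set.seed(5)
  for (i in 1:30) {
    nr <- sample(1:8, 1); nd <- sample(1:8, 1)
    ref <- data.frame(id = seq_len(nr), x = runif(nr, 0, 100),
                      y = runif(nr, 0, 100), area = runif(nr, 10, 300))
    det <- data.frame(id = seq_len(nd), x = runif(nd, 0, 100),
                      y = runif(nd, 0, 100), area = runif(nd, 10, 300))
    m <- matchObjects(det, ref, maxCentroidDistance = 20)
    expect_equal(nrow(m$pairs) + length(m$extra_detected), nd)
    expect_equal(nrow(m$pairs) + length(m$undetected_reference), nr)
    # each id used at most once
    expect_false(any(duplicated(m$pairs$det_id)))
    expect_false(any(duplicated(m$pairs$ref_id)))
  }
})

test_that("agreement reproduces least-squares fits", {
  ref <- data.frame(id = 1:4, x = 1:4 * 10, y = 10, area = c(10, 20, 30, 40))
  m <- matchObjects(ref, ref, maxCentroidDistance = 3)
  a <- agreement(m, "area")
  expect_equal(c(a$slope, a$intercept, a$r_squared), c(1, 0, 1))
  # exact collinear pairs y = 2x
  m2 <- list(pairs = data.frame(ref_id = 1:3, det_id = 1:3,
                                ref_area = 1:3, det_area = c(2, 4, 6),
                                area_dev = c(1, 2, 3)),
             n_ref = 3, n_det = 3)
  a2 <- agreement(m2, "area")
  expect_equal(c(a2$slope, a2$intercept, a2$r_squared), c(2, 0, 1))
  expect_equal(a2$mean_abs_deviation, 2)
  # random pairs vs the closed-form normal equations
  set.seed(15)
  rx <- runif(50, 1, 100); ry <- 1.3 * rx + rnorm(50, 0, 8)
  m3 <- list(pairs = data.frame(ref_id = 1:50, det_id = 1:50,
                                ref_area = rx, det_area = ry,
                                area_dev = ry - rx),
             n_ref = 50, n_det = 50)
  a3 <- agreement(m3, "area")
  sxx <- sum((rx - mean(rx))^2); sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  b1 <- sxy / sxx; b0 <- mean(ry) - b1 * mean(rx)
  r2 <- 1 - sum((ry - b0 - b1 * rx)^2) / sum((ry - mean(ry))^2)
  expect_equal(a3$slope, b1, tolerance = 1e-10)
  expect_equal(a3$intercept, b0, tolerance = 1e-10)
  expect_equal(a3$r_squared, r2, tolerance = 1e-10)
})

test_that("agreement with fewer than two pairs is flagged undefined", {
  m <- list(pairs = data.frame(ref_id = 1, det_id = 1, ref_area = 5,
                               det_area = 6, area_dev = 1),
            n_ref = 3, n_det = 1)
  a <- agreement(m, "area")
  expect_false(a$defined)
  expect_true(is.na(a$slope))
  expect_equal(a$mean_abs_deviation, 1)
})

test_that("replicate averaging gives zero standard error for identical runs", {
  run <- data.frame(id = 1:3, area = c(10, 20, 30))
  avg <- replicateAverage(rep(list(run), 5))
  expect_equal(avg$area, run$area)
  expect_equal(avg$area_se, rep(0, 3))
  two <- replicateAverage(list(data.frame(id = 1, area = 4),
                               data.frame(id = 1, area = 6)))
  expect_equal(two$area, 5)
  set.seed(25)
  runs <- lapply(1:4, function(i)
    data.frame(id = 1:6, area = runif(6, 10, 50)))
  avg2 <- replicateAverage(runs)
  m <- sapply(runs, `[[`, "area")
  expect_equal(avg2$area, rowMeans(m))
  expect_equal(avg2$area_se, apply(m, 1, sd) / 2)
  expect_error(replicateAverage(list(run, data.frame(id = c(1, 2, 9),
                                                     area = 1:3))),
               "aligned")
})

test_that("evaluation reports round-trip through CSV", {
  ref <- data.frame(id = 1:3, x = c(10, 40, 70), y = 10,
                    area = c(100, 50, 80))
  det <- data.frame(id = 1:2, x = c(10, 40), y = c(10, 11),
                    area = c(95, 55))
  m <- matchObjects(det, ref, maxCentroidDistance = 8)
  f <- tempfile(fileext = ".csv")
  writeEvaluationReport(m, f)
  rep <- read.csv(f)
  expect_equal(sum(rep$status == "matched"), 2)
  expect_equal(sum(rep$status == "undetected"), 1)
})
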