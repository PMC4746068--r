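#' Construct a synthetic scene specification
#'
#' See [SceneSpec-class] for the meaning of every field.  Objects are
#' anti-aliased ellipses (edge softness 1 px) rendered over a background
#' with optional linear gradient, radial vignette, Gaussian noise, dark
#' or bright specks, and bright scratch lines.  Overlapping objects are
#' rejected unless `touchingPairs` is set, in which case unions are
#' rendered without an intensity ridge — the hard case for watershed.
#'
#' @param width,height frame size (px).
#' @param objects data.frame with columns `x`, `y`, `a`, `b`, `theta`,
#'   `contrast`, `polarity`.
#' @param backgroundLevel mean background intensity.
#' @param gradientVector,gradientAmplitude linear illumination gradient:
#'   direction and peak-to-peak amplitude as a fraction of the
#'   background level.
#' @param vignetteAmplitude radial fall-off fraction at the frame corners.
#' @param noiseSigma Gaussian noise sd (intensity units).
#' @param nSpecks,speckArea speck artifact count and area range (px^2).
#' @param nScratches,scratchLength,scratchWidth bright scratch lines:
#'   count, length range and width range (px).
#' @param touchingPairs allow overlapping objects.
#' @param maxValue 255 (8-bit, default) or 65535 (16-bit).
#' @param calibration micrometres per pixel.
#' @param seed RNG seed; generation is reproducible given the spec.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(width, height, objects = emptyObjects(),
                      backgroundLevel = 200, gradientVector = c(1, 0),
                      gradientAmplitude = 0, vignetteAmplitude = 0,
                      noiseSigma = 0, nSpecks = 0L, speckArea = c(1, 4),
                      nScratches = 0L, scratchLength = c(40, 120),
                      scratchWidth = c(1, 2), touchingPairs = FALSE,
                      maxValue = 255, calibration = 1, seed = 1L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      objects = objects, backgroundLevel = as.numeric(backgroundLevel),
      gradientVector = as.numeric(gradientVector),
      gradientAmplitude = as.numeric(gradientAmplitude),
      vignetteAmplitude = as.numeric(vignetteAmplitude),
      noiseSigma = as.numeric(noiseSigma), nSpecks = as.integer(nSpecks),
      speckArea = as.numeric(speckArea),
      nScratches = as.integer(nScratches),
      scratchLength = as.numeric(scratchLength),
      scratchWidth = as.numeric(scratchWidth),
      touchingPairs = isTRUE(touchingPairs),
      maxValue = as.numeric(maxValue),
      calibration = as.numeric(calibration), seed = as.integer(seed))
}

#' @rdname sceneSpec
#' @export
emptyObjects <- function() {
  data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
             b = numeric(0), theta = numeric(0), contrast = numeric(0),
             polarity = character(0))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec %d x %d: %d objects, background %g, noise sd %g, seed %d\n",
    object@width, object@height, nrow(object@objects),
    object@backgroundLevel, object@noiseSigma, object@seed))
  if (object@nSpecks || object@nScratches)
    cat(sprintf("  artifacts: %d specks, %d scratch lines\n",
                object@nSpecks, object@nScratches))
})

# max-union soft coverage of one ellipse into an accumulator matrix
.renderEllipse <- function(acc, x0, y0, a, b, theta, amp, W, H) {
  r <- ceiling(max(a, b)) + 2
  js <- max(1, floor(x0 - r)):min(W, ceiling(x0 + r))
  is <- max(1, floor(y0 - r)):min(H, ceiling(y0 + r))
  dx <- outer(rep(1, length(is)), js - x0)
  dy <- outer(is - y0, rep(1, length(js)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  # signed distance to the ellipse boundary, approximated radially
  s <- (sqrt(u^2 + v^2) - 1) * min(a, b)
  cov <- pmin(pmax(0.5 - s, 0), 1)
  acc[is, js] <- pmax(acc[is, js], amp * cov)
  acc
}

.renderSegment <- function(acc, x1, y1, x2, y2, width, amp, W, H) {
  r <- ceiling(width / 2) + 2
  js <- max(1, floor(min(x1, x2) - r)):min(W, ceiling(max(x1, x2) + r))
  is <- max(1, floor(min(y1, y2) - r)):min(H, ceiling(max(y1, y2) + r))
  px <- outer(rep(1, length(is)), js)
  py <- outer(is, rep(1, length(js)))
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  cov <- pmin(pmax(width / 2 + 0.5 - d, 0), 1)
  acc[is, js] <- pmax(acc[is, js], amp * cov)
  acc
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by a [SceneSpec-class] and returns the
#' image together with its analytic ground truth (per object: centre,
#' true area `pi * a * b`, equivalent radius, polarity) and the artifact
#' mask.  Deterministic given the spec: the same spec always produces the
#' identical raster; the truth table does not depend on the noise seed.
#'
#' @param spec a [SceneSpec-class].
#' @return A list with `image` ([Raster-class]), `truth` (data.frame:
#'   `id`, `x`, `y`, `area_px`, `equiv_radius`, `polarity`) and
#'   `artifactMask` ([BinaryMask-class]).
#' @examples
#' sc <- generateScene(scenario("bacterial_like", seed = 7))
#' nrow(sc$truth)
#' @export
generateScene <- function(spec) {
  .checkClass(spec, "SceneSpec", "spec")
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv())
  else old <- NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec@seed)

  W <- spec@width; H <- spec@height
  img <- matrix(spec@backgroundLevel, H, W)

  if (spec@gradientAmplitude > 0 && any(spec@gradientVector != 0)) {
    g <- spec@gradientVector / sqrt(sum(spec@gradientVector^2))
    u <- outer((seq_len(H) - (H + 1) / 2) * g[2],
               (seq_len(W) - (W + 1) / 2) * g[1], `+`)
    span <- max(u) - min(u)
    img <- img + spec@backgroundLevel * spec@gradientAmplitude *
      (u - min(u) - span / 2) / span
  }
  if (spec@vignetteAmplitude > 0) {
    r2 <- outer((seq_len(H) - (H + 1) / 2)^2,
                (seq_len(W) - (W + 1) / 2)^2, `+`)
    img <- img - spec@backgroundLevel * spec@vignetteAmplitude *
      r2 / max(r2)
  }

  dark <- matrix(0, H, W)
  bright <- matrix(0, H, W)
  ob <- spec@objects
  for (k in seq_len(nrow(ob))) {
    if (ob$polarity[k] == "dark")
      dark <- .renderEllipse(dark, ob$x[k], ob$y[k], ob$a[k], ob$b[k],
                             ob$theta[k], ob$contrast[k], W, H)
    else
      bright <- .renderEllipse(bright, ob$x[k], ob$y[k], ob$a[k],
                               ob$b[k], ob$theta[k], ob$contrast[k], W, H)
  }

  adark <- matrix(0, H, W)
  abright <- matrix(0, H, W)
  if (spec@nSpecks > 0) {
    pol <- if (nrow(ob) && mean(ob$polarity == "bright") > 0.5)
      "bright" else "dark"
    for (k in seq_len(spec@nSpecks)) {
      sx <- stats::runif(1, 3, W - 2)
      sy <- stats::runif(1, 3, H - 2)
      sr <- sqrt(stats::runif(1, spec@speckArea[1], spec@speckArea[2]) / pi)
      sc <- stats::runif(1, 20, 60)
      if (pol == "dark")
        adark <- .renderEllipse(adark, sx, sy, sr, sr, 0, sc, W, H)
      else
        abright <- .renderEllipse(abright, sx, sy, sr, sr, 0, sc, W, H)
    }
  }
  if (spec@nScratches > 0) {
    for (k in seq_len(spec@nScratches)) {
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, spec@scratchLength[1], spec@scratchLength[2])
      wid <- stats::runif(1, spec@scratchWidth[1], spec@scratchWidth[2])
      # scratch marks show up white (near-saturated)
      sc <- stats::runif(1, 0.8, 1) * (spec@maxValue - spec@backgroundLevel)
      abright <- .renderSegment(abright,
        cx - cos(ang) * len / 2, cy - sin(ang) * len / 2,
        cx + cos(ang) * len / 2, cy + sin(ang) * len / 2, wid, sc, W, H)
    }
  }
  artifactMask <- (pmax(adark, abright) > 0.25) * 1
  img <- img - pmax(dark, adark) + pmax(bright, abright)

  if (spec@noiseSigma > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSigma), H, W)
  img <- pmin(pmax(round(img), 0), spec@maxValue)

  truth <- data.frame(
    id = seq_len(nrow(ob)), x = ob$x, y = ob$y,
    area_px = pi * ob$a * ob$b, equiv_radius = sqrt(ob$a * ob$b),
    polarity = ob$polarity)
  list(image = Raster(img, calibration = spec@calibration,
                      maxValue = spec@maxValue),
       truth = truth,
       artifactMask = BinaryMask(artifactMask,
                                 calibration = spec@calibration))
}

# rejection-sampled non-overlapping placement; falls back to the most
# isolated of 200 candidates when the frame gets crowded
.placeObjects <- function(n, radii, W, H, gap = 25, margin = 15) {
  x <- numeric(n); y <- numeric(n)
  o <- order(-radii)
  for (t in seq_len(n)) {
    k <- o[t]
    m <- radii[k] + margin
    best <- NULL; bestd <- -Inf
    for (att in 1:200) {
      cx <- stats::runif(1, m, W - m)
      cy <- stats::runif(1, m, H - m)
      if (t == 1) { best <- c(cx, cy); break }
      prev <- o[seq_len(t - 1)]
      d <- min(sqrt((x[prev] - cx)^2 + (y[prev] - cy)^2) -
               (radii[prev] + radii[k]))
      if (d >= gap) { best <- c(cx, cy); break }
      if (d > bestd) { bestd <- d; best <- c(cx, cy) }
    }
    x[k] <- best[1]; y[k] <- best[2]
  }
  cbind(x = x, y = y)
}

#' Named synthetic scenarios emulating the main assay image classes
#'
#' Each scenario returns a fully specified [SceneSpec-class] whose
#' object geometry and artifact content are sampled deterministically
#' from `seed`:
#' \describe{
#'   \item{`tumorsphere_like`}{640 x 640, 12 dark, nearly circular
#'     ellipses (major semi-axis 10-60 px, axis ratio up to 1.28),
#'     contrast 15-40 on an 8-bit background of 200, 10\% linear
#'     illumination gradient, noise sd 2, calibration 2 um/px.}
#'   \item{`bacterial_like`}{256 x 256, 22 bright disks of radius
#'     2-6 px over background 90, 5 bright scratch lines and 10 small
#'     specks, 5\% gradient, noise sd 2.}
#'   \item{`clonogenic_like`}{384 x 384, 40 dark disks of radius
#'     4-12 px, contrast 30-80 on background 180, 20 specks, 8\%
#'     gradient, noise sd 2.}
#'   \item{`touching_pairs`}{160 x 160, one fused pair of equal disks
#'     (radius 12-20 px) at centre distance 1.2-1.6 times the radius,
#'     rendered as a union without an intensity ridge.}
#'   \item{`artifact_stress`}{512 x 512, 8 dark disks of radius
#'     10-20 px plus 520 sub-threshold specks (1-6 px^2) and 5 bright
#'     scratch lines.}
#' }
#'
#' @param name scenario name.
#' @param seed integer; controls both layout sampling and scene noise.
#' @return A [SceneSpec-class].
#' @export
scenario <- function(name = c("tumorsphere_like", "bacterial_like",
                              "clonogenic_like", "touching_pairs",
                              "artifact_stress"), seed = 1L) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop(sprintf(paste0("unknown scenario '%s'; valid scenarios: ",
                        "tumorsphere_like, bacterial_like, ",
                        "clonogenic_like, touching_pairs, ",
                        "artifact_stress"), name[1]), call. = FALSE))
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv())
  else old <- NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  switch(name,
    tumorsphere_like = {
      n <- 12L; W <- H <- 640L
      a <- stats::runif(n, 10, 60)
      b <- a * stats::runif(n, 0.78, 1)
      pos <- .placeObjects(n, a, W, H)
      ob <- data.frame(x = pos[, "x"], y = pos[, "y"], a = a, b = b,
                       theta = stats::runif(n, 0, pi),
                       contrast = stats::runif(n, 15, 40),
                       polarity = "dark")
      sceneSpec(W, H, ob, backgroundLevel = 200,
                gradientVector = c(cos(stats::runif(1, 0, 2 * pi)),
                                   sin(stats::runif(1, 0, 2 * pi))),
                gradientAmplitude = 0.10, noiseSigma = 2,
                calibration = 2, seed = seed)
    },
    bacterial_like = {
      n <- 22L; W <- H <- 256L
      r <- stats::runif(n, 2, 6)
      pos <- .placeObjects(n, r, W, H, gap = 10, margin = 8)
      ob <- data.frame(x = pos[, "x"], y = pos[, "y"], a = r, b = r,
                       theta = 0, contrast = stats::runif(n, 40, 80),
                       polarity = "bright")
      sceneSpec(W, H, ob, backgroundLevel = 90,
                gradientVector = c(1, 0.4), gradientAmplitude = 0.05,
                noiseSigma = 2, nSpecks = 10L, speckArea = c(1, 4),
                nScratches = 5L, scratchLength = c(40, 120),
                scratchWidth = c(0.7, 1.2), seed = seed)
    },
    clonogenic_like = {
      n <- 40L; W <- H <- 384L
      r <- stats::runif(n, 4, 12)
      pos <- .placeObjects(n, r, W, H, gap = 12, margin = 10)
      ob <- data.frame(x = pos[, "x"], y = pos[, "y"], a = r, b = r,
                       theta = 0, contrast = stats::runif(n, 30, 80),
                       polarity = "dark")
      sceneSpec(W, H, ob, backgroundLevel = 180,
                gradientVector = c(0.3, 1), gradientAmplitude = 0.08,
                noiseSigma = 2, nSpecks = 20L, speckArea = c(1, 6),
                seed = seed)
    },
    touching_pairs = {
      W <- H <- 160L
      r <- stats::runif(1, 12, 20)
      f <- stats::runif(1, 1.2, 1.6)
      ang <- stats::runif(1, 0, pi)
      d <- f * r
      cx <- W / 2; cy <- H / 2
      ob <- data.frame(
        x = cx + c(-1, 1) * cos(ang) * d / 2,
        y = cy + c(-1, 1) * sin(ang) * d / 2,
        a = r, b = r, theta = 0, contrast = 60, polarity = "dark")
      sceneSpec(W, H, ob, backgroundLevel = 200, noiseSigma = 2,
                touchingPairs = TRUE, seed = seed)
    },
    artifact_stress = {
      n <- 8L; W <- H <- 512L
      r <- stats::runif(n, 10, 20)
      pos <- .placeObjects(n, r, W, H, gap = 30, margin = 25)
      ob <- data.frame(x = pos[, "x"], y = pos[, "y"], a = r, b = r,
                       theta = 0, contrast = stats::runif(n, 40, 70),
                       polarity = "dark")
      sceneSpec(W, H, ob, backgroundLevel = 180,
                gradientVector = c(1, 0.2), gradientAmplitude = 0.05,
                noiseSigma = 2, nSpecks = 520L, speckArea = c(1, 6),
                nScratches = 5L, scratchLength = c(60, 150),
                scratchWidth = c(1, 2), seed = seed)
    })
}

#' Write a scene (image + truth) to disk
#'
#' Writes the rendered scene as a TIFF next to a CSV of its ground truth,
#' the fixture layout used for batch tests.
#'
#' @param scene result of [generateScene()].
#' @param dir output directory (created if missing).
#' @param name base file name (without extension).
#' @return Named character vector with the `image` and `truth` paths.
#' @export
writeScene <- function(scene, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, ".tif"))
  truthPath <- file.path(dir, paste0(name, "_truth.csv"))
  writeRaster(scene$image, imgPath)
  utils::write.csv(cbind(image = paste0(name, ".tif"), scene$truth),
                   truthPath, row.names = FALSE)
  c(image = imgPath, truth = truthPath)
}
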