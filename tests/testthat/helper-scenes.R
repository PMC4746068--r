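# Shared scene builders for pipeline-level tests.

# n well-separated dark disks on a light background
diskScene <- function(n = 10, radii = NULL, contrast = 40, noise = 2,
                      size = 460, calibration = 2, seed = 1) {
  if (is.null(radii)) {
    set.seed(seed + 1000L)
    radii <- stats::runif(n, 12, 32)
  }
  set.seed(seed + 2000L)
  pos <- ColonyEdge:::.placeObjects(n, radii, size, size,
                                    gap = 20, margin = 12)
  ob <- data.frame(x = pos[, 1], y = pos[, 2], a = radii, b = radii,
                   theta = 0, contrast = contrast, polarity = "dark")
  generateScene(sceneSpec(size, size, ob, backgroundLevel = 200,
                          noiseSigma = noise, calibration = calibration,
                          seed = seed))
}

# tumorsphere-style configuration with denoising/shrink radii adapted to
# small-object scenes (see the methods vignette)
tumorsphereStyle <- function() {
  pipelineConfig(list(
    stageSpec("subtract_background", radius = 80),
    stageSpec("sharpen"),
    stageSpec("enhance_contrast", saturated_fraction = 0.002),
    stageSpec("sobel"),
    stageSpec("gaussian_blur", sigma = 2),
    stageSpec("make_binary"),
    stageSpec("close"), stageSpec("fill_holes"),
    stageSpec("maximum", radius = 2),
    stageSpec("close"), stageSpec("fill_holes"),
    stageSpec("minimum", radius = 4),
    stageSpec("remove_outliers", radius = 5),
    stageSpec("watershed")),
    calibration = 2,
    filter = particleFilter(50, Inf, 0.2, 1),
    lightBackground = TRUE)
}

# fused pair of equal disks; centre distance = f * r
fusedPairMask <- function(r = 14, f = 1.4, size = 96) {
  d <- f * r
  c1 <- size / 2 - d / 2
  c2 <- size / 2 + d / 2
  m <- pmax(diskMatrix(size, size, size / 2, c1, r),
            diskMatrix(size, size, size / 2, c2, r))
  BinaryMask(m)
}
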