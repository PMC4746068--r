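#' @import methods
NULL

#' PixelGrid: common substrate of image-like objects
#'
#' Virtual parent of [Raster-class], [BinaryMask-class] and
#' [LabelMap-class].  A pixel grid is an R matrix (rows = image rows / y,
#' columns = image columns / x) plus a spatial calibration in micrometres
#' per pixel (1 = uncalibrated, measurements reported in pixel units).
#'
#' @slot pixels numeric matrix of pixel values.
#' @slot calibration micrometres per pixel; strictly positive.
#' @keywords classes
#' @exportClass PixelGrid
setClass("PixelGrid",
  representation("VIRTUAL", pixels = "matrix", calibration = "numeric"))

setValidity("PixelGrid", function(object) {
  p <- object@pixels
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("pixel grid must be at least 1 x 1")
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    return("pixel values must be finite numbers")
  if (length(object@calibration) != 1L || !is.finite(object@calibration) ||
      object@calibration <= 0)
    return("calibration must be a single positive number (um/px)")
  TRUE
})

#' Raster: a grayscale image
#'
#' A single-channel grayscale image.  Values are stored as doubles
#' regardless of the nominal bit depth; `maxValue` records the top of the
#' intensity range (255 for 8-bit, 65535 for 16-bit) and is used by
#' operations that clip or rescale to the depth range.
#'
#' @slot maxValue top of the intensity range.
#' @seealso [Raster()], [BinaryMask-class], [LabelMap-class]
#' @keywords classes
#' @exportClass Raster
setClass("Raster", contains = "PixelGrid",
  representation(maxValue = "numeric"))

setValidity("Raster", function(object) {
  if (length(object@maxValue) != 1L || is.na(object@maxValue) ||
      object@maxValue <= 0)
    return("maxValue must be a single positive number")
  TRUE
})

#' BinaryMask: a foreground/background image
#'
#' Pixels are 0 (background) or 1 (foreground = object), independently of
#' display polarity; image export decides how foreground is painted.
#'
#' @seealso [BinaryMask()], [makeBinary()]
#' @keywords classes
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "PixelGrid")

setValidity("BinaryMask", function(object) {
  if (!all(object@pixels %in% c(0, 1)))
    return("a BinaryMask must contain only 0 (background) and 1 (foreground)")
  TRUE
})

#' LabelMap: integer-labeled connected components
#'
#' Background is 0; objects carry consecutive labels 1..n in raster-scan
#' order of their first pixel.
#'
#' @slot nObjects number of labeled objects.
#' @seealso [labelComponents()], [measureParticles()]
#' @keywords classes
#' @exportClass LabelMap
setClass("LabelMap", contains = "PixelGrid",
  representation(nObjects = "integer"))

setValidity("LabelMap", function(object) {
  p <- object@pixels
  n <- object@nObjects
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("nObjects must be a single non-negative integer")
  u <- unique(as.vector(p))
  if (any(u != floor(u)) || any(u < 0) || any(u > n))
    return("labels must be integers in 0..nObjects")
  if (n > 0L && !all(seq_len(n) %in% u))
    return("labels must be consecutive 1..nObjects")
  TRUE
})

#' ParticleFilter: selection criteria for measured objects
#'
#' Size bounds are in calibrated area units (square micrometres when the
#' run is calibrated, square pixels otherwise); circularity bounds are in
#' \[0, 1\].
#'
#' @slot minSize,maxSize calibrated area bounds (maxSize may be `Inf`).
#' @slot minCircularity,maxCircularity circularity bounds in \[0, 1\].
#' @slot excludeEdges drop objects touching the image border.
#' @seealso [particleFilter()], [filterParticles()]
#' @keywords classes
#' @exportClass ParticleFilter
setClass("ParticleFilter",
  representation(minSize = "numeric", maxSize = "numeric",
    minCircularity = "numeric", maxCircularity = "numeric",
    excludeEdges = "logical"))

setValidity("ParticleFilter", function(object) {
  if (object@minSize < 0 || object@minSize > object@maxSize)
    return("need 0 <= minSize <= maxSize")
  if (object@minCircularity < 0 || object@maxCircularity > 1 ||
      object@minCircularity > object@maxCircularity)
    return("need 0 <= minCircularity <= maxCircularity <= 1")
  if (length(object@excludeEdges) != 1L || is.na(object@excludeEdges))
    return("excludeEdges must be TRUE or FALSE")
  TRUE
})

#' PipelineConfig: an ordered, parameterized stage list
#'
#' The processing recipe of a run: stages applied in order (each a list
#' with elements `name`, `params`, `enabled`), the spatial calibration, the
#' particle filter, the background polarity, and whether intensity
#' measurements are redirected to the original image.
#'
#' Stage order must be valid: no binary-domain stage may precede
#' `make_binary`, no grayscale-only stage may follow it, and `make_binary`
#' appears exactly once.
#'
#' @slot stages ordered list of stage specifications.
#' @slot calibration micrometres per pixel for measurements.
#' @slot filter a [ParticleFilter-class].
#' @slot lightBackground `TRUE` when objects are dark on a light
#'   background (the image is inverted before background subtraction).
#' @slot redirectToOriginal measure intensities on the original image.
#' @seealso [pipelineConfig()], [pipelinePreset()], [runPipeline()]
#' @keywords classes
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(stages = "list", calibration = "numeric",
    filter = "ParticleFilter", lightBackground = "logical",
    redirectToOriginal = "logical"))

setValidity("PipelineConfig", function(object) {
  msg <- .checkStages(object@stages)
  if (!is.null(msg)) return(msg)
  if (length(object@calibration) != 1L || object@calibration <= 0)
    return("calibration must be a single positive number")
  if (length(object@lightBackground) != 1L || is.na(object@lightBackground))
    return("lightBackground must be TRUE or FALSE")
  if (length(object@redirectToOriginal) != 1L ||
      is.na(object@redirectToOriginal))
    return("redirectToOriginal must be TRUE or FALSE")
  TRUE
})

#' SceneSpec: recipe for a synthetic scene
#'
#' Describes a synthetic image with known ground truth: elliptical objects
#' over a low-contrast background, smooth uneven illumination (linear
#' gradient and/or radial vignette), Gaussian sensor noise, and speck and
#' scratch artifacts.  Generation is deterministic given `seed`.
#'
#' @slot width,height frame size in pixels.
#' @slot objects data.frame with columns `x`, `y` (centre, 1-based px),
#'   `a`, `b` (semi-axes, px), `theta` (orientation, radians), `contrast`
#'   (amplitude, intensity units), `polarity` (`"dark"` or `"bright"`).
#' @slot backgroundLevel mean background intensity.
#' @slot gradientVector direction of the linear illumination gradient.
#' @slot gradientAmplitude peak-to-peak gradient, as a fraction of
#'   `backgroundLevel`.
#' @slot vignetteAmplitude radial fall-off at the corners, as a fraction
#'   of `backgroundLevel`.
#' @slot noiseSigma Gaussian noise standard deviation.
#' @slot nSpecks,speckArea number of speck artifacts and their area range
#'   (px^2); specks take the majority object polarity.
#' @slot nScratches,scratchLength,scratchWidth bright scratch-line count
#'   and geometry ranges (px).
#' @slot touchingPairs allow overlapping objects (rendered as unions).
#' @slot maxValue intensity range top (255 or 65535).
#' @slot calibration micrometres per pixel.
#' @slot seed RNG seed for noise and artifact placement.
#' @seealso [sceneSpec()], [scenario()], [generateScene()]
#' @keywords classes
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(width = "integer", height = "integer",
    objects = "data.frame", backgroundLevel = "numeric",
    gradientVector = "numeric", gradientAmplitude = "numeric",
    vignetteAmplitude = "numeric", noiseSigma = "numeric",
    nSpecks = "integer", speckArea = "numeric",
    nScratches = "integer", scratchLength = "numeric",
    scratchWidth = "numeric", touchingPairs = "logical",
    maxValue = "numeric", calibration = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@width < 1L || object@height < 1L)
    return("frame must be at least 1 x 1")
  ob <- object@objects
  if (nrow(ob)) {
    need <- c("x", "y", "a", "b", "theta", "contrast", "polarity")
    if (!all(need %in% names(ob)))
      return(paste("objects needs columns:", paste(need, collapse = ", ")))
    if (any(ob$x < 1 | ob$x > object@width | ob$y < 1 | ob$y > object@height))
      return("object centres must lie inside the frame")
    if (any(ob$contrast <= 0)) return("contrast amplitudes must be > 0")
    if (any(ob$a <= 0 | ob$b <= 0)) return("semi-axes must be > 0")
    if (!all(ob$polarity %in% c("dark", "bright")))
      return("polarity must be 'dark' or 'bright'")
  }
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@backgroundLevel < 0 || object@backgroundLevel > object@maxValue)
    return("backgroundLevel must lie in [0, maxValue]")
  TRUE
})
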