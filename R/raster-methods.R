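#' Create a grayscale Raster
#'
#' @param pixels numeric matrix (rows = image rows / y, columns = x).
#' @param calibration micrometres per pixel (1 = uncalibrated).
#' @param maxValue top of the intensity range (255 for 8-bit images).
#' @return A [Raster-class] object.
#' @examples
#' r <- Raster(matrix(runif(100, 0, 255), 10, 10))
#' r
#' @export
Raster <- function(pixels, calibration = 1, maxValue = 255) {
  new("Raster", pixels = .asPixelMatrix(pixels),
      calibration = as.numeric(calibration), maxValue = as.numeric(maxValue))
}

#' Create a BinaryMask
#'
#' @param pixels matrix of 0/1 values (or a logical matrix).
#' @param calibration micrometres per pixel.
#' @return A [BinaryMask-class] object.
#' @examples
#' m <- BinaryMask(matrix(c(0, 1, 1, 0), 2, 2))
#' sum(pixelData(m))
#' @export
BinaryMask <- function(pixels, calibration = 1) {
  p <- .asPixelMatrix(pixels)
  storage.mode(p) <- "double"
  new("BinaryMask", pixels = p, calibration = as.numeric(calibration))
}

#' Create a LabelMap
#'
#' @param pixels matrix of integer labels, 0 = background.
#' @param calibration micrometres per pixel.
#' @param nObjects number of objects; defaults to `max(pixels)`.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(pixels, calibration = 1, nObjects = NULL) {
  p <- .asPixelMatrix(pixels)
  storage.mode(p) <- "double"
  if (is.null(nObjects)) nObjects <- as.integer(max(0, p))
  new("LabelMap", pixels = p, calibration = as.numeric(calibration),
      nObjects = as.integer(nObjects))
}

.asPixelMatrix <- function(pixels) {
  if (is.logical(pixels)) {
    m <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
    return(m)
  }
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "double"
  pixels
}

#' @describeIn pixelData method for all pixel grids
#' @export
setMethod("pixelData", "PixelGrid", function(x) x@pixels)

#' @describeIn calibration method for all pixel grids
#' @export
setMethod("calibration", "PixelGrid", function(x) x@calibration)

#' @describeIn maxValue method for Raster
#' @export
setMethod("maxValue", "Raster", function(x) x@maxValue)

#' @describeIn nObjects method for LabelMap
#' @export
setMethod("nObjects", "LabelMap", function(x) x@nObjects)

#' @export
setMethod("dim", "PixelGrid", function(x) dim(x@pixels))

setMethod("show", "Raster", function(object) {
  p <- object@pixels
  cat(sprintf("Raster %d x %d (h x w), range [%.4g, %.4g], maxValue %g\n",
              nrow(p), ncol(p), min(p), max(p), object@maxValue))
  cat(sprintf("  calibration: %g um/px\n", object@calibration))
})

setMethod("show", "BinaryMask", function(object) {
  p <- object@pixels
  cat(sprintf("BinaryMask %d x %d, %d foreground px (%.1f%%)\n",
              nrow(p), ncol(p), sum(p), 100 * mean(p)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap %d x %d, %d objects\n",
              nrow(object@pixels), ncol(object@pixels), object@nObjects))
})

# rebuild an output object like `x` but with new pixels
.likeRaster <- function(x, pixels) {
  if (is(x, "Raster"))
    new("Raster", pixels = pixels, calibration = x@calibration,
        maxValue = x@maxValue)
  else new("BinaryMask", pixels = pixels, calibration = x@calibration)
}

.checkClass <- function(x, what, arg) {
  if (!is(x, what))
    stop(sprintf("'%s' must be a %s, got %s", arg, what, class(x)[1]),
         call. = FALSE)
  invisible(x)
}
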