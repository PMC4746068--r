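#' Pixel data of an image-like object
#'
#' @param x a [PixelGrid-class] derivative.
#' @return The pixel matrix (rows = image rows, columns = image columns).
#' @examples
#' r <- Raster(matrix(0, 4, 6))
#' dim(pixelData(r))
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' Spatial calibration (micrometres per pixel)
#'
#' @param x a [PixelGrid-class] derivative.
#' @return A single number; 1 means uncalibrated (pixel units).
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' Top of the intensity range of a Raster
#'
#' @param x a [Raster-class].
#' @return 255 for 8-bit data, 65535 for 16-bit, or any positive number.
#' @export
setGeneric("maxValue", function(x) standardGeneric("maxValue"))

#' Number of labeled objects in a LabelMap
#'
#' @param x a [LabelMap-class].
#' @return Integer count of objects (labels 1..n).
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
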