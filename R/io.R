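#' Read an image file as a Raster
#'
#' Reads TIFF, PNG or JPEG (via EBImage).  Color images are reduced to
#' one channel first.  File values are rescaled from EBImage's \[0, 1\]
#' convention to \[0, maxValue\].  Spatial calibration is supplied here
#' (not read from TIFF tags).
#'
#' @param path image file.
#' @param calibration micrometres per pixel.
#' @param maxValue intensity range top of the file's bit depth (255 for
#'   8-bit, 65535 for 16-bit).
#' @param channel channel selector for color images (see
#'   [toGrayscale()]).
#' @return A [Raster-class].
#' @export
readRaster <- function(path, calibration = 1, maxValue = 255,
                       channel = "luminance") {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    d <- d[, , 1:3, drop = FALSE]
    arr <- array(0, c(dim(d)[2], dim(d)[1], 3))
    for (k in 1:3) arr[, , k] <- t(d[, , k]) * maxValue
    return(toGrayscale(arr, channel = channel, calibration = calibration,
                       maxValue = maxValue))
  }
  Raster(t(d) * maxValue, calibration = calibration, maxValue = maxValue)
}

#' Write a Raster to an image file
#'
#' Format follows the file extension (.tif/.tiff, .png, .jpg/.jpeg).
#' 16-bit output (TIFF/PNG) is chosen when `maxValue(x) > 255`.
#'
#' @param x a [Raster-class] or [BinaryMask-class] (masks are written
#'   with foreground black on white, the display convention for detected
#'   colonies).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeRaster <- function(x, path) {
  if (is(x, "BinaryMask")) {
    p <- 1 - x@pixels           # display polarity: objects black
    mv <- 1
  } else {
    .checkClass(x, "Raster", "x")
    p <- x@pixels
    mv <- x@maxValue
  }
  img <- EBImage::Image(t(pmin(pmax(p / mv, 0), 1)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    EBImage::writeImage(img, path, bits.per.sample =
                          if (mv > 255) 16L else 8L)
  else EBImage::writeImage(img, path)
  invisible(path)
}

#' Export a LabelMap as a 16-bit TIFF label image
#'
#' Pixel value = object label (0 = background), stored losslessly for up
#' to 65535 objects.
#'
#' @param labels a [LabelMap-class].
#' @param path output TIFF file.
#' @return The path, invisibly.
#' @export
writeLabelTiff <- function(labels, path) {
  .checkClass(labels, "LabelMap", "labels")
  if (labels@nObjects > 65535L) stop("more than 65535 labels")
  img <- EBImage::Image(t(labels@pixels) / 65535)
  EBImage::writeImage(img, path, bits.per.sample = 16L)
  invisible(path)
}
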