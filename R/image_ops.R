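#' Extract a grayscale channel from a color image
#'
#' Color images are h x w x 3 arrays (red, green, blue planes).  The
#' luminance mix is the ITU-R BT.601 weighting 0.299 R + 0.587 G +
#' 0.114 B.  A grayscale input ([Raster-class] or h x w matrix) is
#' returned unchanged for any requested channel.
#'
#' @param image a [Raster-class], a matrix, or an h x w x 3 array.
#' @param channel one of `"luminance"`, `"red"`, `"green"`, `"blue"`.
#' @param calibration,maxValue used when `image` is a bare matrix/array.
#' @return A [Raster-class].
#' @examples
#' rgb <- array(0, c(4, 4, 3)); rgb[, , 1] <- 7; rgb[, , 3] <- 9
#' pixelData(toGrayscale(rgb, "red"))[1, 1]
#' @export
toGrayscale <- function(image, channel = c("luminance", "red", "green",
                                           "blue"),
                        calibration = 1, maxValue = 255) {
  channel <- match.arg(channel)
  if (is(image, "Raster")) return(image)
  if (is.matrix(image))
    return(Raster(image, calibration = calibration, maxValue = maxValue))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must have 1 or 3 channels (matrix or h x w x 3 array)")
  p <- switch(channel,
    red = image[, , 1], green = image[, , 2], blue = image[, , 3],
    luminance = 0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3])
  Raster(p, calibration = calibration, maxValue = maxValue)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image
#' with a ball-shaped structuring element of the given radius (Sternberg's
#' rolling-ball construction) and subtracts it, removing smooth
#' illumination trends while preserving objects narrower than the ball.
#' With `lightBackground = TRUE` the image is inverted first, so dark
#' objects on a light background come out as bright objects on a dark,
#' near-zero background.  A practical starting radius is the average
#' object radius.
#'
#' @param x a [Raster-class].
#' @param radius ball radius in pixels (>= 1).
#' @param lightBackground objects darker than the background?
#' @return A [Raster-class]; values clipped to >= 0.
#' @examples
#' r <- Raster(matrix(50, 32, 32))
#' range(pixelData(subtractBackground(r, 10)))  # constant -> all zero
#' @export
subtractBackground <- function(x, radius, lightBackground = FALSE) {
  .checkClass(x, "Raster", "x")
  if (length(radius) != 1L || !is.finite(radius) || radius < 1)
    stop("radius must be a single number >= 1")
  p <- x@pixels
  if (lightBackground) p <- x@maxValue - p
  bg <- cpp_ball_open(p, radius)
  .likeRaster(x, pmax(p - bg, 0))
}

#' Sharpen an image (3x3 high-boost kernel)
#'
#' Convolution with the 3x3 kernel having centre weight 12 and neighbour
#' weight -1, normalized by 4 (sums to 1, so flat regions are unchanged).
#' Borders are handled by edge replication; the result is clipped to the
#' depth range \[0, maxValue\].
#'
#' @param x a [Raster-class].
#' @return A [Raster-class].
#' @export
sharpenImage <- function(x) {
  .checkClass(x, "Raster", "x")
  k <- matrix(-1, 3, 3)
  k[2, 2] <- 12
  out <- cpp_conv2(x@pixels, k / 4)
  .likeRaster(x, pmin(pmax(out, 0), x@maxValue))
}

#' Linear contrast enhancement with saturation
#'
#' Rescales intensities linearly so that the `saturatedFraction / 2` and
#' `1 - saturatedFraction / 2` quantiles map to 0 and `maxValue`; values
#' outside are clipped (that fraction of pixels saturates).
#'
#' @param x a [Raster-class].
#' @param saturatedFraction proportion of pixels allowed to saturate,
#'   in \[0, 0.5); 0.002 reproduces the usual "0.2%" display enhancement.
#' @return A [Raster-class].
#' @export
enhanceContrast <- function(x, saturatedFraction = 0.002) {
  .checkClass(x, "Raster", "x")
  if (length(saturatedFraction) != 1L || is.na(saturatedFraction) ||
      saturatedFraction < 0 || saturatedFraction >= 0.5)
    stop("saturatedFraction must lie in [0, 0.5)")
  v <- sort(as.vector(x@pixels))
  n <- length(v)
  k <- floor(n * saturatedFraction / 2)
  lo <- v[k + 1L]
  hi <- v[n - k]
  if (hi <= lo) return(x)
  out <- (x@pixels - lo) / (hi - lo) * x@maxValue
  .likeRaster(x, pmin(pmax(out, 0), x@maxValue))
}

#' Sobel edge magnitude
#'
#' Gradient magnitude sqrt(Gx^2 + Gy^2) with the standard 3x3 Sobel
#' kernels; borders by edge replication.  The output is not clipped:
#' edge magnitudes may exceed the input depth range.
#'
#' @param x a [Raster-class].
#' @return A [Raster-class] of edge magnitudes.
#' @export
sobelEdges <- function(x) {
  .checkClass(x, "Raster", "x")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx
  ky <- t(kx)                                                 # d/dy
  gx <- cpp_conv2(x@pixels, kx)
  gy <- cpp_conv2(x@pixels, ky)
  .likeRaster(x, sqrt(gx^2 + gy^2))
}

#' Gaussian blur
#'
#' Separable Gaussian convolution; the kernel is truncated at
#' `ceiling(3 * sigma)` and normalized to sum 1.  Borders by edge
#' replication.
#'
#' Applied to a [BinaryMask-class], this is the binary smoothing step of
#' the macro: the 0/255 mask is blurred and automatically re-binarized
#' (IsoData).  Isolated speckle dilutes quadratically under the blur and
#' falls below the re-binarization threshold, while coherent edge curves
#' only thin — this is the pipeline's main speckle-noise rejection.
#'
#' @param x a [Raster-class] or [BinaryMask-class].
#' @param sigma standard deviation in pixels (> 0).
#' @return Same class as `x`.
#' @export
gaussianBlur <- function(x, sigma) {
  if (!is(x, "Raster") && !is(x, "BinaryMask"))
    stop("'x' must be a Raster or BinaryMask")
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single number > 0")
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  if (is(x, "BinaryMask")) {
    b <- cpp_sepconv(x@pixels * 255, k)
    if (max(b) <= min(b))
      return(BinaryMask(matrix(0, nrow(b), ncol(b)), x@calibration))
    return(BinaryMask((b > isodataThreshold(b)) * 1, x@calibration))
  }
  .likeRaster(x, cpp_sepconv(x@pixels, k))
}

#' Automatic binarization
#'
#' Global thresholding of the intensity distribution.  The default is the
#' iterative intermeans (IsoData) rule: starting from the overall mean,
#' the threshold is repeatedly replaced by the mean of the class means
#' below and above it until it stabilizes.  Pixels strictly above the
#' threshold become foreground.  A constant image yields an all-background
#' mask.  `method = "otsu"` uses Otsu's criterion (via EBImage);
#' `method = "triangle"` uses the triangle geometric rule, which keys the
#' threshold off the background peak and is the better choice for
#' strongly skewed histograms such as edge-magnitude images, where
#' intermeans midpoints between weak and strong edges and can drop
#' faint objects.
#'
#' @param x a [Raster-class].
#' @param method `"isodata"` (default), `"otsu"` or `"triangle"`.
#' @return A [BinaryMask-class].
#' @examples
#' r <- Raster(matrix(rep(c(10, 200), each = 50), 10, 10))
#' mean(pixelData(makeBinary(r)))  # half the pixels are foreground
#' @export
makeBinary <- function(x, method = c("isodata", "otsu", "triangle")) {
  .checkClass(x, "Raster", "x")
  method <- match.arg(method)
  p <- x@pixels
  if (max(p) <= min(p))
    return(BinaryMask(matrix(0, nrow(p), ncol(p)), x@calibration))
  t <- switch(method,
    isodata = isodataThreshold(p),
    otsu = EBImage::otsu(EBImage::Image(t(p) / x@maxValue),
                         range = c(0, 1)) * x@maxValue,
    triangle = triangleThreshold(p))
  BinaryMask((p > t) * 1, x@calibration)
}

#' Triangle threshold of a set of values
#'
#' The geometric triangle rule on a 256-bin histogram: a line is drawn
#' from the histogram peak to the far end of the longer tail; the
#' threshold is the bin with maximal perpendicular distance below that
#' line.
#'
#' @param values numeric vector or matrix.
#' @param nbins number of histogram bins.
#' @return The threshold on the value scale.
#' @export
triangleThreshold <- function(values, nbins = 256L) {
  v <- as.vector(values)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * nbins) + 1L, 1L),
                     nbins), nbins)
  peak <- which.max(h)
  nz <- which(h > 0)
  # work on the longer tail; mirror so the tail is to the right
  flip <- (peak - nz[1]) > (nz[length(nz)] - peak)
  if (flip) { h <- rev(h); peak <- nbins - peak + 1L }
  end <- max(which(h > 0))
  if (end <= peak) return(lo + (peak - 0.5) / nbins * (hi - lo))
  b <- peak:end
  # distance below the line (peak, h[peak]) -- (end, 0)
  d <- (end - peak) * (h[peak] - h[b]) - h[peak] * (b - peak)
  best <- b[which.max(d)]
  if (flip) best <- nbins - best + 1L
  lo + (best - 0.5) / nbins * (hi - lo)
}

#' IsoData (iterative intermeans) threshold of a set of values
#'
#' @param values numeric vector or matrix.
#' @return The converged threshold.
#' @export
isodataThreshold <- function(values) {
  v <- as.vector(values)
  t <- mean(v)
  for (i in 1:200) {
    below <- v[v <= t]
    above <- v[v > t]
    if (!length(above) || !length(below)) break
    t2 <- (mean(below) + mean(above)) / 2
    if (abs(t2 - t) < 1e-7) return(t2)
    t <- t2
  }
  t
}

#' Morphological closing of a binary mask
#'
#' `iterations` dilations followed by the same number of erosions with a
#' 3x3 square structuring element; bridges small gaps in contours.
#' Closing is extensive: the output always contains the input foreground.
#'
#' @param mask a [BinaryMask-class].
#' @param iterations number of dilate/erode passes (>= 1).
#' @return A [BinaryMask-class].
#' @export
closeMask <- function(mask, iterations = 1) {
  .checkClass(mask, "BinaryMask", "mask")
  if (length(iterations) != 1L || iterations < 1)
    stop("iterations must be >= 1")
  d <- cpp_morph3x3(mask@pixels, 1L, as.integer(iterations))
  e <- cpp_morph3x3(d, 0L, as.integer(iterations))
  # closing is extensive by construction; enforce against border clamping
  BinaryMask(pmax(e, mask@pixels), mask@calibration)
}

#' Fill enclosed holes in a binary mask
#'
#' Background components that are not 4-connected to the image border
#' become foreground; border-connected background is left unchanged.
#' Idempotent.
#'
#' @param mask a [BinaryMask-class].
#' @return A [BinaryMask-class].
#' @export
fillHoles <- function(mask) {
  .checkClass(mask, "BinaryMask", "mask")
  BinaryMask(EBImage::fillHull(mask@pixels), mask@calibration)
}

#' Grayscale/binary dilation or erosion with a digital disk
#'
#' Maximum (dilation) or minimum (erosion) over a digital disk of the
#' given radius (pixels with centre distance <= radius + 0.5).  Works on
#' rasters and binary masks alike; the ImageJ "Maximum"/"Minimum"
#' commands.
#'
#' @param x a [Raster-class] or [BinaryMask-class].
#' @param radius disk radius in pixels (>= 1).
#' @param mode `"maximum"` or `"minimum"`.
#' @return Same class as `x`.
#' @export
rankFilter <- function(x, radius, mode = c("maximum", "minimum")) {
  if (!is(x, "Raster") && !is(x, "BinaryMask"))
    stop("'x' must be a Raster or BinaryMask")
  mode <- match.arg(mode)
  if (length(radius) != 1L || !is.finite(radius) || radius < 1)
    stop("radius must be a single number >= 1")
  out <- cpp_rank_disk(x@pixels, radius, if (mode == "maximum") 1L else 0L)
  .likeRaster(x, out)
}

#' Median-deviation outlier removal
#'
#' Each pixel deviating from its disk-neighborhood median by more than
#' `threshold` in the given polarity is replaced by that median (the
#' ImageJ "Remove Outliers" denoising step).  On a binary mask the
#' comparison is made on the 8-bit scale (foreground = 255), so the
#' default threshold deletes foreground specks smaller than about half
#' the neighborhood.
#'
#' @param x a [Raster-class] or [BinaryMask-class].
#' @param radius neighborhood disk radius in pixels (>= 1).
#' @param threshold deviation threshold in intensity units (>= 0);
#'   default 50 on the 8-bit scale.
#' @param polarity `"bright"` removes pixels above the median,
#'   `"dark"` pixels below it.
#' @return Same class as `x`.
#' @export
removeOutliers <- function(x, radius, threshold = 50,
                           polarity = c("bright", "dark")) {
  if (!is(x, "Raster") && !is(x, "BinaryMask"))
    stop("'x' must be a Raster or BinaryMask")
  polarity <- match.arg(polarity)
  if (length(radius) != 1L || !is.finite(radius) || radius < 1)
    stop("radius must be a single number >= 1")
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be >= 0")
  if (is(x, "BinaryMask")) {
    out <- cpp_remove_outliers(x@pixels * 255, radius, threshold,
                               polarity == "bright") / 255
    return(BinaryMask(round(out), x@calibration))
  }
  .likeRaster(x, cpp_remove_outliers(x@pixels, radius, threshold,
                                     polarity == "bright"))
}
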