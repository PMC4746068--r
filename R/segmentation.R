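#' Euclidean distance map of a binary mask
#'
#' Distance from each foreground pixel to the nearest background pixel
#' (exact Euclidean metric); background pixels are 0.  The substrate of
#' binary watershed splitting.
#'
#' @param mask a [BinaryMask-class].
#' @return A [Raster-class] of distances.
#' @export
distanceMap <- function(mask) {
  .checkClass(mask, "BinaryMask", "mask")
  d <- EBImage::imageData(EBImage::distmap(mask@pixels, metric = "euclidean"))
  Raster(d, calibration = mask@calibration, maxValue = max(1, d))
}

#' Seed points for watershed splitting
#'
#' Finds one seed per regional maximum of a distance map, merging maxima
#' whose peaks differ by at most `tolerance` along a connecting path (the
#' noise-tolerance rule of ImageJ's maximum finder): candidate maxima are
#' visited in decreasing height order, each floods its within-tolerance
#' region, and a flood that reaches ground claimed by a higher maximum
#' produces no seed.  The seed position is the centroid of the peak
#' plateau.
#'
#' @param edm a [Raster-class] distance map (e.g. from [distanceMap()]).
#' @param tolerance peak-merging tolerance (>= 0); the default 0.5
#'   suppresses plateau double-seeding from near-integer distance maps.
#' @return A data.frame with columns `x`, `y` (1-based pixel coordinates
#'   of seed centroids), one row per seed.
#' @export
findSeeds <- function(edm, tolerance = 0.5) {
  .checkClass(edm, "Raster", "edm")
  if (length(tolerance) != 1L || is.na(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0")
  s <- cpp_find_seeds(edm@pixels, tolerance)
  as.data.frame(s$centroids)
}

#' Split touching objects by binary watershed
#'
#' Floods the inverted Euclidean distance map from the seeds of
#' [findSeeds()]; where floods from different seeds meet, a one-pixel-wide
#' divide line is set to background, separating fused roughly-circular
#' objects.  Objects containing a single seed are returned unchanged.
#' Flooding order ties are broken by (distance, raster index), so the
#' result is deterministic.  Reliable only for circular/elliptical
#' objects; elongated shapes may be oversegmented.
#'
#' @param mask a [BinaryMask-class].
#' @param tolerance seed-merging tolerance passed to seed finding.
#' @return A [BinaryMask-class] with divide lines removed from the
#'   foreground.
#' @examples
#' g <- expand.grid(i = 1:40, j = 1:70)
#' fused <- matrix(as.numeric((g$i - 20)^2 + (g$j - 22)^2 <= 144 |
#'                            (g$i - 20)^2 + (g$j - 48)^2 <= 144), 40, 70)
#' nObjects(labelComponents(binaryWatershed(BinaryMask(fused))))  # 2
#' @export
binaryWatershed <- function(mask, tolerance = 0.5) {
  .checkClass(mask, "BinaryMask", "mask")
  if (sum(mask@pixels) == 0) return(mask)
  edm <- distanceMap(mask)
  s <- cpp_find_seeds(edm@pixels, tolerance)
  lab <- cpp_watershed(edm@pixels, s$seed_map)
  BinaryMask((lab > 0) * 1, mask@calibration)
}

#' Label connected components
#'
#' Deterministic connected-component labeling: objects are numbered in
#' raster-scan order of their first pixel.  Foreground objects normally
#' use 8-connectivity (the particle-analysis convention, with 4-connected
#' background as its dual).
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 8 (default) or 4.
#' @return A [LabelMap-class].
#' @export
labelComponents <- function(mask, connectivity = 8) {
  .checkClass(mask, "BinaryMask", "mask")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- cpp_label(mask@pixels, as.integer(connectivity))
  LabelMap(lab, calibration = mask@calibration,
           nObjects = attr(lab, "n"))
}
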