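#' Construct a particle filter
#'
#' @param minSize,maxSize calibrated area bounds (um^2 when calibrated,
#'   px^2 otherwise); `maxSize` may be `Inf`.
#' @param minCircularity,maxCircularity circularity bounds in \[0, 1\].
#' @param excludeEdges drop objects touching the image border.
#' @return A [ParticleFilter-class].
#' @examples
#' particleFilter(minSize = 50, minCircularity = 0.2)
#' @export
particleFilter <- function(minSize = 0, maxSize = Inf, minCircularity = 0,
                           maxCircularity = 1, excludeEdges = FALSE) {
  new("ParticleFilter", minSize = as.numeric(minSize),
      maxSize = as.numeric(maxSize),
      minCircularity = as.numeric(minCircularity),
      maxCircularity = as.numeric(maxCircularity),
      excludeEdges = as.logical(excludeEdges))
}

setMethod("show", "ParticleFilter", function(object) {
  cat(sprintf(
    "ParticleFilter: size [%g, %g], circularity [%g, %g]%s\n",
    object@minSize, object@maxSize, object@minCircularity,
    object@maxCircularity,
    if (object@excludeEdges) ", excluding edge objects" else ""))
})

#' Measure labeled particles
#'
#' Computes, for every labeled object: area (pixel count times
#' calibration^2), perimeter (Freeman chain-code length of the outer
#' contour: orthogonal step 1, diagonal sqrt(2), times calibration),
#' circularity `min(1, 4 * pi * area / perimeter^2)` evaluated in pixel
#' units (ImageJ's capped shape score; a single-pixel object counts as
#' circular), centroid, bounding box, border contact, and mean/integrated
#' intensity over a redirect image (typically the original, so intensity
#' is read from unprocessed data).  Inner contours of holes do not
#' contribute to the perimeter; pipelines fill holes before measuring.
#'
#' @param labels a [LabelMap-class].
#' @param redirect optional [Raster-class] with the same dimensions, the
#'   intensity source.
#' @param calibration micrometres per pixel; defaults to the label map's.
#' @return A data.frame with one row per object: `id`, `area`,
#'   `perimeter`, `circularity`, `x`, `y` (centroid, 1-based px),
#'   `bbox_x0`, `bbox_y0`, `bbox_w`, `bbox_h` (px), `touches_edge`,
#'   `mean_intensity`, `integrated_intensity` (NA without redirect).
#' @export
measureParticles <- function(labels, redirect = NULL,
                             calibration = NULL) {
  .checkClass(labels, "LabelMap", "labels")
  if (is.null(calibration)) calibration <- labels@calibration
  if (!is.null(redirect)) {
    .checkClass(redirect, "Raster", "redirect")
    if (!identical(dim(redirect), dim(labels)))
      stop("redirect image dimensions must match the label map")
  }
  n <- labels@nObjects
  cols <- c("id", "area", "perimeter", "circularity", "x", "y",
            "bbox_x0", "bbox_y0", "bbox_w", "bbox_h", "touches_edge",
            "mean_intensity", "integrated_intensity")
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    out$touches_edge <- logical(0)
    return(out)
  }
  p <- labels@pixels
  H <- nrow(p); W <- ncol(p)
  idx <- which(p > 0)
  li <- as.integer(p[idx])
  rows <- ((idx - 1L) %% H) + 1L
  colsx <- ((idx - 1L) %/% H) + 1L

  areaPx <- tabulate(li, nbins = n)
  storage.mode(p) <- "integer"
  perPx <- cpp_perimeters(p, n)
  circ <- ifelse(perPx > 0, pmin(1, 4 * pi * areaPx / perPx^2), 1)

  cx <- as.vector(tapply(colsx, li, mean))
  cy <- as.vector(tapply(rows, li, mean))
  x0 <- as.vector(tapply(colsx, li, min))
  x1 <- as.vector(tapply(colsx, li, max))
  y0 <- as.vector(tapply(rows, li, min))
  y1 <- as.vector(tapply(rows, li, max))
  edge <- as.vector(tapply(rows == 1L | rows == H | colsx == 1L |
                           colsx == W, li, any))
  if (!is.null(redirect)) {
    vals <- redirect@pixels[idx]
    tot <- as.vector(tapply(vals, li, sum))
    mn <- tot / areaPx
  } else {
    tot <- rep(NA_real_, n)
    mn <- rep(NA_real_, n)
  }
  data.frame(id = seq_len(n),
             area = areaPx * calibration^2,
             perimeter = perPx * calibration,
             circularity = circ,
             x = cx, y = cy,
             bbox_x0 = x0, bbox_y0 = y0,
             bbox_w = x1 - x0 + 1, bbox_h = y1 - y0 + 1,
             touches_edge = edge,
             mean_intensity = mn,
             integrated_intensity = tot)
}

#' Filter measured particles
#'
#' Keeps the records satisfying the size range, the circularity range,
#' and (when requested) not touching the image border.  A pure subset:
#' surviving rows are returned unmodified, in their original order.
#'
#' @param records data.frame from [measureParticles()].
#' @param filter a [ParticleFilter-class].
#' @return The surviving subset of `records`.
#' @export
filterParticles <- function(records, filter) {
  .checkClass(filter, "ParticleFilter", "filter")
  if (nrow(records) == 0L) return(records)
  keep <- records$area >= filter@minSize & records$area <= filter@maxSize &
    records$circularity >= filter@minCircularity &
    records$circularity <= filter@maxCircularity &
    (!filter@excludeEdges | !records$touches_edge)
  records[keep, , drop = FALSE]
}

#' Summary statistics of a particle table
#'
#' Count, mean/median and quartiles of area and perimeter, as used for
#' per-image summaries and boxplots.  An empty table yields `n = 0` with
#' all statistics NA.
#'
#' @param records data.frame from [measureParticles()].
#' @return A one-row data.frame: `n`, `mean_area`, `median_area`,
#'   `q25_area`, `q75_area`, `mean_perimeter`, `median_perimeter`,
#'   `q25_perimeter`, `q75_perimeter`.
#' @export
summarizeParticles <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(n = 0L, mean_area = NA_real_, median_area = NA_real_,
                      q25_area = NA_real_, q75_area = NA_real_,
                      mean_perimeter = NA_real_, median_perimeter = NA_real_,
                      q25_perimeter = NA_real_, q75_perimeter = NA_real_))
  qa <- stats::quantile(records$area, c(0.25, 0.75), names = FALSE)
  qp <- stats::quantile(records$perimeter, c(0.25, 0.75), names = FALSE)
  data.frame(n = nrow(records),
             mean_area = mean(records$area),
             median_area = stats::median(records$area),
             q25_area = qa[1], q75_area = qa[2],
             mean_perimeter = mean(records$perimeter),
             median_perimeter = stats::median(records$perimeter),
             q25_perimeter = qp[1], q75_perimeter = qp[2])
}

#' Write a particle table to CSV
#'
#' Fixed column layout: `image`, then the columns of
#' [measureParticles()].
#'
#' @param records particle data.frame.
#' @param file output path.
#' @param image image name recorded in the first column.
#' @return The file path, invisibly.
#' @export
writeParticles <- function(records, file, image = NA_character_) {
  out <- cbind(image = image, records)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
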