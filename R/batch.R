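# 3x5 bitmap digits for burning object numbers into overlays
.digitFont <- c(
  "111101101101111", "010110010010111", "111001111100111",
  "111001111001111", "101101111001001", "111100111001111",
  "111100111101111", "111001001001001", "111101111101111",
  "111101111001111")

.burnNumber <- function(red, green, blue, number, x, y) {
  H <- nrow(red); W <- ncol(red)
  digits <- strsplit(as.character(number), "")[[1]]
  x0 <- round(x) - 2 * length(digits)
  y0 <- round(y) - 2
  for (d in seq_along(digits)) {
    bits <- as.integer(strsplit(.digitFont[as.integer(digits[d]) + 1],
                                "")[[1]])
    for (r in 0:4) for (c in 0:2) {
      if (!bits[r * 3 + c + 1]) next
      i <- y0 + r; j <- x0 + (d - 1) * 4 + c
      if (i >= 1 && i <= H && j >= 1 && j <= W) {
        red[i, j] <- 1; green[i, j] <- 1; blue[i, j] <- 0
      }
    }
  }
  list(red, green, blue)
}

#' Burn detected object outlines and numbers into an image
#'
#' Writes the original image with each object's boundary traced in red
#' and its label number burned in yellow near the centroid — the visual
#' check that detection matches the eye.  With an empty label map the
#' output is simply the input image.
#'
#' @param image the original [Raster-class].
#' @param labels a [LabelMap-class] of the same dimensions.
#' @param path output PNG (or TIFF/JPEG) file.
#' @return The path, invisibly.
#' @export
renderOverlay <- function(image, labels, path) {
  .checkClass(image, "Raster", "image")
  .checkClass(labels, "LabelMap", "labels")
  if (!identical(dim(image), dim(labels)))
    stop("image and label map dimensions differ")
  g <- pmin(pmax(image@pixels / image@maxValue, 0), 1)
  red <- green <- blue <- g
  lab <- labels@pixels
  if (labels@nObjects > 0) {
    H <- nrow(lab); W <- ncol(lab)
    shift <- function(m, dr, dc) {
      out <- m
      ri <- pmin(pmax(seq_len(H) + dr, 1), H)
      ci <- pmin(pmax(seq_len(W) + dc, 1), W)
      out[] <- m[ri, ci]
      out
    }
    boundary <- lab > 0 & (shift(lab, 1, 0) != lab |
                           shift(lab, -1, 0) != lab |
                           shift(lab, 0, 1) != lab |
                           shift(lab, 0, -1) != lab)
    # border pixels of border-touching objects are boundary too
    boundary[c(1, H), ] <- boundary[c(1, H), ] | lab[c(1, H), ] > 0
    boundary[, c(1, W)] <- boundary[, c(1, W)] | lab[, c(1, W)] > 0
    red[boundary] <- 1; green[boundary] <- 0; blue[boundary] <- 0
    rec <- measureParticles(labels, calibration = 1)
    for (k in seq_len(nrow(rec))) {
      out <- .burnNumber(red, green, blue, rec$id[k], rec$x[k], rec$y[k])
      red <- out[[1]]; green <- out[[2]]; blue <- out[[3]]
    }
  }
  arr <- array(0, c(ncol(red), nrow(red), 3))
  arr[, , 1] <- t(red); arr[, , 2] <- t(green); arr[, , 3] <- t(blue)
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}

#' Analyze a folder of images with one configuration
#'
#' High-throughput batch mode: every readable image in the folder is run
#' through the same pipeline; per-image particle CSVs, a combined CSV and
#' (optionally) outline overlays are written.  A failing image is
#' recorded and skipped, never fatal.  The whole batch is a pure function
#' of the images and the configuration, so reruns produce byte-identical
#' CSVs.
#'
#' @param folder directory containing the images (all of one size class;
#'   non-image files are ignored with a warning).
#' @param cfg a [PipelineConfig-class].
#' @param out output directory (created); `NULL` disables file output.
#' @param overlay also write outline overlays.
#' @param maxValue bit-depth range of the input files.
#' @param pattern regular expression selecting image files.
#' @return A list of class `BatchResult`: `images` (per-image data.frame:
#'   `path`, `n`, summary statistics, `status`), `particles` (combined
#'   table with an `image` column), `failures` (paths).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' for (s in 1:3)
#'   writeScene(generateScene(scenario("touching_pairs", seed = s)),
#'              dir, sprintf("scene%02d", s))
#' res <- runBatch(dir, pipelinePreset("clonogenic"))
#' res$images$n
#' @export
runBatch <- function(folder, cfg, out = NULL, overlay = FALSE,
                     maxValue = 255,
                     pattern = "\\.(tif|tiff|png|jpg|jpeg)$") {
  .checkClass(cfg, "PipelineConfig", "cfg")
  if (!dir.exists(folder)) stop(sprintf("no such folder: %s", folder))
  all <- list.files(folder, full.names = TRUE)
  all <- all[!dir.exists(all)]
  files <- sort(all[grepl(pattern, all, ignore.case = TRUE)])
  skipped <- setdiff(all, files)
  skipped <- skipped[!grepl("_truth\\.csv$", skipped)]
  if (length(skipped))
    warning(sprintf("ignoring %d non-image file(s) in %s",
                    length(skipped), folder))
  if (!length(files))
    stop(sprintf("folder contains no readable images: %s", folder))
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  rows <- list(); tabs <- list(); failures <- character(0)
  for (f in files) {
    base <- tools::file_path_sans_ext(basename(f))
    img <- tryCatch(readRaster(f, calibration = cfg@calibration,
                               maxValue = maxValue),
                    error = function(e) e)
    res <- if (inherits(img, "error")) img
           else tryCatch(runPipeline(img, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, f)
      rows[[f]] <- data.frame(path = f, summarizeParticles(
        measureParticles(LabelMap(matrix(0, 1, 1)))),
        status = paste("failed:", conditionMessage(res)))
      next
    }
    s <- summarizeParticles(res$particles)
    rows[[f]] <- data.frame(path = f, s, status = "ok")
    if (nrow(res$particles))
      tabs[[f]] <- cbind(image = basename(f), res$particles)
    if (!is.null(out)) {
      writeParticles(res$particles,
                     file.path(out, paste0(base, "_particles.csv")),
                     image = basename(f))
      if (overlay)
        renderOverlay(img, res$labels,
                      file.path(out, paste0(base, "_overlay.png")))
    }
  }
  images <- do.call(rbind, rows)
  rownames(images) <- NULL
  particles <- if (length(tabs)) do.call(rbind, tabs)
               else cbind(image = character(0),
                          measureParticles(LabelMap(matrix(0, 1, 1))))
  rownames(particles) <- NULL
  if (!is.null(out))
    utils::write.csv(particles, file.path(out, "combined_particles.csv"),
                     row.names = FALSE)
  structure(list(images = images, particles = particles,
                 failures = failures), class = "BatchResult")
}

#' @export
print.BatchResult <- function(x, ...) {
  cat(sprintf("BatchResult: %d image(s), %d object(s), %d failure(s)\n",
              nrow(x$images), nrow(x$particles), length(x$failures)))
  invisible(x)
}
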