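#' Convert a ground-truth table to a reference table for matching
#'
#' @param truth truth data.frame from [generateScene()] (`id`, `x`, `y`,
#'   `area_px`, `equiv_radius`, ...).
#' @param calibration micrometres per pixel of the detection run, so
#'   that reference areas are in the same calibrated units as measured
#'   particle areas.
#' @return data.frame with columns `id`, `x`, `y`, `area` (calibrated)
#'   and `radius_px` (matching radius in pixels).
#' @export
truthAsReference <- function(truth, calibration = 1) {
  data.frame(id = truth$id, x = truth$x, y = truth$y,
             area = truth$area_px * calibration^2,
             radius_px = truth$equiv_radius)
}

#' Match detected objects to reference objects
#'
#' Greedy assignment by centroid proximity implementing the standard
#' matching protocol of digital-vs-manual colony comparisons, including its split and merge rules:
#' \itemize{
#'   \item references are processed in decreasing area order (ties by
#'     id); each takes the largest-area unassigned detected object whose
#'     centroid lies within the reference's matching radius;
#'   \item split rule: when a detection method fragments one object, the
#'     largest fragment is the match and the remaining fragments are
#'     counted as extra objects (they receive additional ids after the
#'     last reference id);
#'   \item merge rule: when one detected object covers several
#'     references, it pairs with the largest reference and the smaller
#'     references are counted as undetected.
#' }
#' The matching radius of a reference is
#' `max(radius_px, maxCentroidDistance)`; `radius_px` defaults to
#' `sqrt(area / pi)` (pixel units) when the column is absent.
#'
#' @param detected particle table ([measureParticles()] format: needs
#'   `id`, `x`, `y`, `area`).
#' @param reference reference table (`id`, `x`, `y`, `area`, optionally
#'   `radius_px`).
#' @param maxCentroidDistance floor on the matching radius, in pixels
#'   (> 0).
#' @return A list of class `MatchResult`: `pairs` (data.frame `ref_id`,
#'   `det_id`, `ref_area`, `det_area`, `area_dev`), `extra_detected`
#'   (detected ids), `extra_assigned_ids` (their additional object
#'   numbers), `undetected_reference` (reference ids), `n_ref`, `n_det`.
#' @examples
#' ref <- data.frame(id = 1, x = 10, y = 10, area = 100)
#' det <- data.frame(id = 1:2, x = c(10, 12), y = c(10, 9),
#'                   area = c(70, 30))
#' matchObjects(det, ref, maxCentroidDistance = 10)$extra_detected
#' @export
matchObjects <- function(detected, reference, maxCentroidDistance = 10) {
  if (length(maxCentroidDistance) != 1L || !is.finite(maxCentroidDistance)
      || maxCentroidDistance <= 0)
    stop("maxCentroidDistance must be a single number > 0")
  radius <- if ("radius_px" %in% names(reference)) reference$radius_px
            else sqrt(reference$area / pi)
  ord <- order(-reference$area, reference$id)
  nd <- nrow(detected)
  assigned <- rep(FALSE, nd)
  pr <- pd <- integer(0)
  for (i in ord) {
    rr <- max(radius[i], maxCentroidDistance)
    if (!nd) break
    d <- sqrt((detected$x - reference$x[i])^2 +
              (detected$y - reference$y[i])^2)
    cand <- which(!assigned & d <= rr)
    if (!length(cand)) next
    best <- cand[order(-detected$area[cand], detected$id[cand])][1]
    assigned[best] <- TRUE
    pr <- c(pr, i); pd <- c(pd, best)
  }
  pairs <- data.frame(
    ref_id = reference$id[pr], det_id = detected$id[pd],
    ref_area = reference$area[pr], det_area = detected$area[pd],
    area_dev = detected$area[pd] - reference$area[pr])
  if ("perimeter" %in% names(detected) &&
      "perimeter" %in% names(reference)) {
    pairs$ref_perimeter <- reference$perimeter[pr]
    pairs$det_perimeter <- detected$perimeter[pd]
  }
  extra <- detected$id[!assigned]
  lastRef <- if (nrow(reference)) max(reference$id) else 0
  out <- list(pairs = pairs,
              extra_detected = extra,
              extra_assigned_ids = lastRef + seq_along(extra),
              undetected_reference =
                reference$id[!reference$id %in% pairs$ref_id],
              n_ref = nrow(reference), n_det = nd)
  class(out) <- "MatchResult"
  out
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf(
    "MatchResult: %d pairs, %d extra detected, %d undetected (ref %d, det %d)\n",
    nrow(x$pairs), length(x$extra_detected),
    length(x$undetected_reference), x$n_ref, x$n_det))
  invisible(x)
}

#' Quantify agreement between detected and reference measurements
#'
#' Ordinary least-squares fit of the detected measure on the reference
#' measure over matched pairs (the digital-vs-manual comparison plot),
#' plus the mean absolute per-pair deviation.  Perfect agreement gives
#' slope 1, intercept 0, R-squared 1.
#'
#' @param result a `MatchResult` from [matchObjects()].
#' @param measure `"area"` or `"perimeter"`.
#' @return A one-row data.frame: `slope`, `intercept`, `r_squared`,
#'   `mean_abs_deviation`, `n_pairs`, `n_ref`, `n_det`, `defined`
#'   (FALSE with fewer than 2 pairs, in which case the fit columns are
#'   NA).
#' @export
agreement <- function(result, measure = c("area", "perimeter")) {
  measure <- match.arg(measure)
  rc <- paste0("ref_", measure)
  dc <- paste0("det_", measure)
  p <- result$pairs
  if (!all(c(rc, dc) %in% names(p)))
    stop(sprintf("pairs carry no %s measurements", measure))
  if (nrow(p) < 2)
    return(data.frame(slope = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_,
                      mean_abs_deviation =
                        if (nrow(p)) mean(abs(p[[dc]] - p[[rc]]))
                        else NA_real_,
                      n_pairs = nrow(p), n_ref = result$n_ref,
                      n_det = result$n_det, defined = FALSE))
  fit <- stats::lm(p[[dc]] ~ p[[rc]])
  tss <- sum((p[[dc]] - mean(p[[dc]]))^2)
  rsq <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = rsq,
             mean_abs_deviation = mean(abs(p[[dc]] - p[[rc]])),
             n_pairs = nrow(p), n_ref = result$n_ref,
             n_det = result$n_det, defined = TRUE)
}

#' Average measurements over replicate analysis runs
#'
#' Repeated analyses of the same image are averaged per object; the
#' per-object mean and standard error across runs are returned.  A fully
#' deterministic method yields standard error 0 for every object.
#'
#' @param runs non-empty list of measurement tables sharing the same
#'   `id` column; all numeric columns except `id` are averaged.
#' @return data.frame with `id` and, for each measured column, `<col>`
#'   (the mean across runs) and `<col>_se` (standard error; NA for a
#'   single run).
#' @export
replicateAverage <- function(runs) {
  if (!length(runs)) stop("runs must be a non-empty list")
  ids <- runs[[1]]$id
  for (r in runs)
    if (!identical(sort(r$id), sort(ids)))
      stop("runs are not aligned: object ids differ between tables")
  runs <- lapply(runs, function(r) r[match(ids, r$id), , drop = FALSE])
  k <- length(runs)
  numcols <- names(runs[[1]])[vapply(runs[[1]], is.numeric, TRUE)]
  numcols <- setdiff(numcols, "id")
  out <- data.frame(id = ids)
  for (col in numcols) {
    m <- sapply(runs, function(r) r[[col]])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    out[[col]] <- rowMeans(m)
    out[[paste0(col, "_se")]] <- if (k > 1)
      apply(m, 1, stats::sd) / sqrt(k)
    else NA_real_
  }
  out
}

#' Write an evaluation report to CSV
#'
#' One row per reference object with its match outcome, followed by rows
#' for extra detected objects (additional object numbers).
#'
#' @param result a `MatchResult` from [matchObjects()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeEvaluationReport <- function(result, file) {
  p <- result$pairs
  rows <- data.frame(ref_id = p$ref_id, det_id = p$det_id,
                     status = "matched", ref_area = p$ref_area,
                     det_area = p$det_area, area_dev = p$area_dev)
  if (length(result$undetected_reference))
    rows <- rbind(rows, data.frame(
      ref_id = result$undetected_reference, det_id = NA,
      status = "undetected", ref_area = NA, det_area = NA,
      area_dev = NA))
  if (length(result$extra_detected))
    rows <- rbind(rows, data.frame(
      ref_id = result$extra_assigned_ids,
      det_id = result$extra_detected, status = "extra",
      ref_area = NA, det_area = NA, area_dev = NA))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
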