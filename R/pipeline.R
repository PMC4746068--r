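# Stage registry: every runnable pipeline stage, its pixel domain and its
# implementation.  Domains: "gray" (Raster only), "binary" (BinaryMask
# only), "either", "binarize" (Raster -> BinaryMask).
.stageRegistry <- list(
  subtract_background = list(domain = "gray",
    fun = function(x, params, cfg)
      subtractBackground(x, radius = params$radius,
                         lightBackground = cfg@lightBackground)),
  sharpen = list(domain = "gray",
    fun = function(x, params, cfg) sharpenImage(x)),
  enhance_contrast = list(domain = "gray",
    fun = function(x, params, cfg)
      enhanceContrast(x, saturatedFraction = params$saturated_fraction)),
  sobel = list(domain = "gray",
    fun = function(x, params, cfg) sobelEdges(x)),
  gaussian_blur = list(domain = "either",
    fun = function(x, params, cfg) gaussianBlur(x, sigma = params$sigma)),
  make_binary = list(domain = "binarize",
    fun = function(x, params, cfg)
      makeBinary(x, method = if (is.null(params$method)) "isodata"
                             else params$method)),
  close = list(domain = "binary",
    fun = function(x, params, cfg)
      closeMask(x, iterations = if (is.null(params$iterations)) 1
                                else params$iterations)),
  fill_holes = list(domain = "binary",
    fun = function(x, params, cfg) fillHoles(x)),
  maximum = list(domain = "either",
    fun = function(x, params, cfg)
      rankFilter(x, radius = params$radius, mode = "maximum")),
  minimum = list(domain = "either",
    fun = function(x, params, cfg)
      rankFilter(x, radius = params$radius, mode = "minimum")),
  remove_outliers = list(domain = "either",
    fun = function(x, params, cfg)
      removeOutliers(x, radius = params$radius,
        threshold = if (is.null(params$threshold)) 50 else params$threshold,
        polarity = if (is.null(params$polarity)) "bright"
                   else params$polarity)),
  watershed = list(domain = "binary",
    fun = function(x, params, cfg)
      binaryWatershed(x, tolerance = if (is.null(params$tolerance)) 0.5
                                     else params$tolerance))
)

#' Registered pipeline stage names
#'
#' @return Character vector of stage names accepted in a
#'   [PipelineConfig-class].
#' @export
stageNames <- function() names(.stageRegistry)

#' Specify one pipeline stage
#'
#' @param name a registered stage name (see [stageNames()]).
#' @param ... stage parameters (e.g. `radius`, `sigma`, `tolerance`).
#' @param enabled run this stage?  Disabled stages are skipped.
#' @return A stage specification (named list).
#' @export
stageSpec <- function(name, ..., enabled = TRUE) {
  if (!name %in% names(.stageRegistry))
    stop(sprintf("unknown stage '%s'; valid stages: %s", name,
                 paste(names(.stageRegistry), collapse = ", ")))
  list(name = name, params = list(...), enabled = isTRUE(enabled))
}

# NULL when the stage list is valid, otherwise an error message.
# Order rule: grayscale-only stages before make_binary, binary-only after,
# make_binary exactly once.
.checkStages <- function(stages) {
  if (!length(stages)) return("pipeline needs at least one stage")
  nm <- vapply(stages, function(s) s$name %||% "", "")
  bad <- setdiff(nm, names(.stageRegistry))
  if (length(bad))
    return(sprintf("unknown stage(s): %s; valid stages: %s",
                   paste(unique(bad), collapse = ", "),
                   paste(names(.stageRegistry), collapse = ", ")))
  dom <- vapply(nm, function(n) .stageRegistry[[n]]$domain, "")
  ib <- which(nm == "make_binary")
  if (length(ib) != 1L)
    return("pipeline must contain exactly one make_binary stage")
  if (any(dom[seq_along(nm) < ib] == "binary"))
    return("binary stages (close, fill_holes, watershed) cannot precede make_binary")
  if (any(dom[seq_along(nm) > ib] == "gray"))
    return("grayscale stages cannot follow make_binary")
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a pipeline configuration
#'
#' @param stages list of stage specifications from [stageSpec()].
#' @param calibration micrometres per pixel used for measurements.
#' @param filter a [ParticleFilter-class].
#' @param lightBackground objects darker than the background?
#' @param redirectToOriginal measure intensity on the original image?
#' @return A validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig(list(stageSpec("gaussian_blur", sigma = 1),
#'                            stageSpec("make_binary")))
#' @export
pipelineConfig <- function(stages, calibration = 1,
                           filter = particleFilter(),
                           lightBackground = FALSE,
                           redirectToOriginal = TRUE) {
  new("PipelineConfig", stages = stages,
      calibration = as.numeric(calibration), filter = filter,
      lightBackground = as.logical(lightBackground),
      redirectToOriginal = as.logical(redirectToOriginal))
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: %d stages, calibration %g um/px%s\n",
              length(object@stages), object@calibration,
              if (object@lightBackground) ", light background" else ""))
  for (s in object@stages) {
    p <- if (length(s$params))
      paste0("(", paste(names(s$params), unlist(s$params), sep = "=",
                        collapse = ", "), ")")
    else ""
    cat(sprintf("  %s %s%s\n", s$name, p,
                if (s$enabled) "" else "  [disabled]"))
  }
  show(object@filter)
})

#' Run the edge-detection pipeline on one image
#'
#' Applies the configured stages in order (skipping disabled ones), then
#' labels the resulting mask (8-connectivity), measures all objects with
#' intensity optionally redirected to the original image, and applies the
#' particle filter.  The run is deterministic: identical image and
#' configuration give bit-identical outputs.
#'
#' @param image a [Raster-class] (grayscale; use [toGrayscale()] first
#'   for color images).
#' @param cfg a [PipelineConfig-class].
#' @param keepDiagnostics retain every intermediate image (memory-hungry;
#'   off by default).
#' @return A list with elements `mask` ([BinaryMask-class]), `labels`
#'   ([LabelMap-class]), `particles` (filtered measurement table),
#'   `allParticles` (pre-filter table), and `diagnostics` (named list of
#'   intermediates when requested).
#' @examples
#' sc <- generateScene(scenario("touching_pairs", seed = 1))
#' res <- runPipeline(sc$image, pipelinePreset("tumorsphere"))
#' nrow(res$particles)
#' @export
runPipeline <- function(image, cfg, keepDiagnostics = FALSE) {
  .checkClass(image, "Raster", "image")
  .checkClass(cfg, "PipelineConfig", "cfg")
  validObject(cfg)
  x <- image
  diagnostics <- if (keepDiagnostics) list(`00_input` = image) else list()
  for (k in seq_along(cfg@stages)) {
    s <- cfg@stages[[k]]
    if (!isTRUE(s$enabled)) next
    entry <- .stageRegistry[[s$name]]
    dom <- entry$domain
    isBin <- is(x, "BinaryMask")
    if (dom == "gray" && isBin)
      stop(sprintf("stage '%s' needs a grayscale image", s$name))
    if ((dom == "binary") && !isBin)
      stop(sprintf("stage '%s' needs a binary mask", s$name))
    x <- entry$fun(x, s$params, cfg)
    if (keepDiagnostics)
      diagnostics[[sprintf("%02d_%s", k, s$name)]] <- x
  }
  if (!is(x, "BinaryMask"))
    stop("pipeline did not produce a binary mask (is make_binary disabled?)")
  mask <- BinaryMask(x@pixels, cfg@calibration)
  labels <- labelComponents(mask, connectivity = 8)
  all <- measureParticles(labels,
    redirect = if (cfg@redirectToOriginal) image else NULL,
    calibration = cfg@calibration)
  kept <- filterParticles(all, cfg@filter)
  list(mask = mask, labels = labels, particles = kept, allParticles = all,
       diagnostics = diagnostics)
}

#' Enable or disable a pipeline stage
#'
#' Returns a modified copy of the configuration with every stage of the
#' given name switched on or off; the input configuration is unchanged.
#' Skipping stages adapts the pipeline to special cases (e.g. no
#' watershed for non-circular cells, no hole filling for tube networks).
#'
#' @param cfg a [PipelineConfig-class].
#' @param stage stage name present in `cfg`.
#' @param enabled new state.
#' @return The modified [PipelineConfig-class].
#' @export
toggleStage <- function(cfg, stage, enabled) {
  .checkClass(cfg, "PipelineConfig", "cfg")
  nm <- vapply(cfg@stages, `[[`, "", "name")
  hit <- which(nm == stage)
  if (!length(hit))
    stop(sprintf("stage '%s' is not part of this pipeline (stages: %s)",
                 stage, paste(unique(nm), collapse = ", ")))
  for (i in hit) cfg@stages[[i]]$enabled <- isTRUE(enabled)
  cfg
}

#' Grid search over pipeline parameters against ground truth
#'
#' Automates the manual trial-and-error choice of stage parameters:
#' every grid point is evaluated by running the modified pipeline and
#' scoring detected objects against a reference table with the F1 measure
#' of object matching (via [matchObjects()]).  Deterministic ordering:
#' rows are ranked by decreasing F1, ties broken by grid order.
#'
#' @param image a [Raster-class].
#' @param base a [PipelineConfig-class] to modify.
#' @param grid named list; names are `"stage.param"` (e.g.
#'   `"gaussian_blur.sigma"`), values are the candidate vectors.  The full
#'   factorial crossing is evaluated.
#' @param truth reference table with columns `id`, `x`, `y`, `area`
#'   (calibrated units; see [truthAsReference()]).
#' @param maxCentroidDistance matching radius floor in pixels.
#' @return A data.frame: one row per grid point with its parameter values,
#'   detection counts (`n_detected`, `tp`, `fp`, `fn`) and `f1`, ranked
#'   best first.
#' @export
sweepParameters <- function(image, base, grid, truth,
                            maxCentroidDistance = 10) {
  .checkClass(base, "PipelineConfig", "base")
  if (!length(grid)) stop("grid must contain at least one parameter")
  if (is.null(truth) || nrow(truth) == 0L)
    stop("truth table must contain at least one reference object")
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  res <- data.frame(pts, n_detected = 0L, tp = 0L, fp = 0L, fn = 0L,
                    f1 = 0)
  nm <- vapply(base@stages, `[[`, "", "name")
  for (r in seq_len(nrow(pts))) {
    cfg <- base
    for (col in names(pts)) {
      parts <- strsplit(col, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("grid name '%s' is not of the form stage.param", col))
      hit <- which(nm == parts[1])
      if (!length(hit))
        stop(sprintf("stage '%s' not in base pipeline", parts[1]))
      for (i in hit) cfg@stages[[i]]$params[[parts[2]]] <- pts[r, col]
    }
    out <- runPipeline(image, cfg)
    m <- matchObjects(out$particles, truth,
                      maxCentroidDistance = maxCentroidDistance)
    tp <- nrow(m$pairs)
    fp <- length(m$extra_detected)
    fn <- length(m$undetected_reference)
    res$n_detected[r] <- nrow(out$particles)
    res$tp[r] <- tp; res$fp[r] <- fp; res$fn[r] <- fn
    res$f1[r] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  res[order(-res$f1, seq_len(nrow(res))), , drop = FALSE]
}

# ---- configuration serialization (YAML) ------------------------------

#' Serialize / restore a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML (including infinite
#' size bounds), so presets can be exported, edited and shared as plain
#' text.
#'
#' @param cfg a [PipelineConfig-class].
#' @param file path to a YAML file.
#' @return `writeConfig` returns the path invisibly; `readConfig` the
#'   restored [PipelineConfig-class].
#' @export
writeConfig <- function(cfg, file) {
  .checkClass(cfg, "PipelineConfig", "cfg")
  f <- cfg@filter
  obj <- list(
    stages = lapply(cfg@stages, function(s)
      list(name = s$name, params = s$params, enabled = s$enabled)),
    calibration = cfg@calibration,
    light_background = cfg@lightBackground,
    redirect_to_original = cfg@redirectToOriginal,
    filter = list(min_size = f@minSize, max_size = f@maxSize,
                  min_circularity = f@minCircularity,
                  max_circularity = f@maxCircularity,
                  exclude_edges = f@excludeEdges))
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname writeConfig
#' @export
readConfig <- function(file) {
  obj <- yaml::read_yaml(file)
  fl <- obj$filter
  pipelineConfig(
    stages = lapply(obj$stages, function(s)
      list(name = s$name,
           params = if (is.null(s$params)) list() else s$params,
           enabled = isTRUE(s$enabled))),
    calibration = obj$calibration,
    filter = particleFilter(fl$min_size, fl$max_size, fl$min_circularity,
                            fl$max_circularity, fl$exclude_edges),
    lightBackground = obj$light_background,
    redirectToOriginal = obj$redirect_to_original)
}
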