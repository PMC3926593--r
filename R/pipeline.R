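#' Feature plane for the pipeline
#'
#' `"excess_green"` gives the excess-green index (marker dark, vegetation
#' bright); `"red_band"` gives the raw red channel (marker bright).
#'
#' @param img an [RGBImage-class].
#' @param feature `"excess_green"` or `"red_band"`.
#' @return numeric matrix.
#' @export
featurePlane <- function(img, feature = c("excess_green", "red_band")) {
  feature <- match.arg(feature)
  if (feature == "excess_green") excessIndex(img, "green")
  else splitBands(img)$red
}

#' Assemble and validate a pipeline configuration
#'
#' @param feature `"excess_green"` (default) or `"red_band"`.
#' @param reference a [MarkerReference-class].
#' @param threshold a [ThresholdModel-class] or a single number (default
#'   the shipped 2000).
#' @param roi optional `c(x0, y0, width, height)` crop applied before run
#'   detection.
#' @param interpolation `"linear"`, `"previous"` or `"none"`: the hybrid
#'   correction strategy used by [runSeries()].
#' @param datePattern regular expression with one capture group
#'   extracting `YYYY-MM-DD` from frame filenames.
#' @param verbose log each frame's detected run to stderr.
#' @return a validated config (list with class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(feature = c("excess_green", "red_band"),
                           reference, threshold = thresholdModel(),
                           roi = NULL,
                           interpolation = c("linear", "previous", "none"),
                           datePattern = "(\\d{4}-\\d{2}-\\d{2})",
                           verbose = FALSE) {
  feature <- match.arg(feature)
  interpolation <- match.arg(interpolation)
  if (!is(reference, "MarkerReference"))
    stopInput("'reference' must be a MarkerReference")
  if (!is(threshold, "ThresholdModel")) {
    assertScalarNumber(threshold, "threshold", positive = TRUE)
    threshold <- thresholdModel(threshold)
  }
  if (!is.null(roi) && (length(roi) != 4L || any(roi < 1)))
    stopInput("'roi' must be c(x0, y0, width, height), all >= 1")
  structure(list(feature = feature, reference = reference,
                 threshold = threshold, roi = roi,
                 interpolation = interpolation, datePattern = datePattern,
                 verbose = isTRUE(verbose)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys: `feature`, `threshold` (number), `interpolation`,
#' `roi` (list of x0, y0, width, height), `date_pattern`, and a
#' `reference` block with `initial_px`, `initial_cm`, `initial_crop_cm`,
#' `total_cm`, `buried_cm`, `stripe_cm`, `marker_width_px`. Missing keys
#' fall back to the defaults of [pipelineConfig()] and
#' [markerReference()].
#'
#' @param path YAML file path.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopInput("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  rb <- y$reference
  if (is.null(rb$initial_px))
    stopInput("config must provide reference: initial_px")
  refArgs <- list(initialPx = rb$initial_px)
  if (!is.null(rb$total_cm)) refArgs$totalCm <- rb$total_cm
  if (!is.null(rb$buried_cm)) refArgs$buriedCm <- rb$buried_cm
  if (!is.null(rb$initial_cm)) refArgs$initialCm <- rb$initial_cm
  if (!is.null(rb$initial_crop_cm)) refArgs$initialCropCm <- rb$initial_crop_cm
  if (!is.null(rb$stripe_cm)) refArgs$stripeCm <- rb$stripe_cm
  if (!is.null(rb$marker_width_px)) refArgs$markerWidthPx <- rb$marker_width_px
  args <- list(reference = do.call(markerReference, refArgs))
  if (!is.null(y$feature)) args$feature <- y$feature
  if (!is.null(y$threshold)) args$threshold <- y$threshold
  if (!is.null(y$interpolation)) args$interpolation <- y$interpolation
  if (!is.null(y$roi)) args$roi <- unlist(y$roi)
  if (!is.null(y$date_pattern)) args$datePattern <- y$date_pattern
  if (!is.null(y$verbose)) args$verbose <- y$verbose
  do.call(pipelineConfig, args)
}

#' Estimate crop height from a single frame
#'
#' Runs the full measurement chain: feature plane, marker-kernel
#' filtering (the response is negated in red-band mode, where the bar is
#' bright on a dark surround), thresholding, longest-vertical-run
#' detection within the optional ROI, and pixel-to-centimetre height
#' conversion against the calibration reference.
#'
#' @param img an [RGBImage-class] or a path to a PNG/JPEG frame.
#' @param config a `"PipelineConfig"` from [pipelineConfig()].
#' @return one-row data.frame: `estimated_cm`, `detected_px`, `column`,
#'   `top`, `bottom`.
#' @export
estimateFrame <- function(img, config) {
  if (!inherits(config, "PipelineConfig"))
    stopInput("'config' must be a PipelineConfig")
  frameId <- "<in-memory frame>"
  if (is.character(img)) {
    frameId <- img
    img <- readRGBImage(img)
  }
  plane <- featurePlane(img, config$feature)
  k <- modifiedKernel(config$reference@markerWidthPx)
  resp <- convolveImage(plane, k)
  if (config$feature == "red_band") resp <- -resp
  mask <- applyThreshold(resp, config$threshold)
  run <- tryCatch(
    longestVerticalRuns(mask, roi = config$roi, n = 1),
    cropheight_detection_error = function(e)
      stopDetection("frame %s: %s", frameId, conditionMessage(e)))
  detected <- min(run$length, config$reference@initialPx)
  if (config$verbose)
    message(sprintf("frame %s: run col %d rows %d-%d (%d px, clamped %g px)",
                    frameId, run$column, run$top, run$bottom, run$length,
                    detected))
  data.frame(estimated_cm = computeHeight(config$reference, detected),
             detected_px = detected, column = run$column,
             top = run$top, bottom = run$bottom)
}

#' Run the pipeline over a directory of daily frames
#'
#' Estimates every readable frame (dates parsed from filenames), attaches
#' sensor logs, flags unreliable days from the rain gauge (and, in
#' red-band mode, the pyranometer), applies the configured hybrid
#' interpolation, and -- when a reference CSV is given -- computes
#' per-day relative errors and their mean/sd. Frames in which no marker
#' is found are kept with an `NA` estimate and flagged so the correction
#' fills them in.
#'
#' @param imageDir directory of PNG/JPEG frames.
#' @param config a `"PipelineConfig"`.
#' @param sensorCsv optional CSV with columns `date`, `light_wm2`,
#'   `rain_mmh`.
#' @param referenceCsv optional CSV with columns `date`, `reference_cm`
#'   (and optionally `condition`), e.g. the `truth.csv` of
#'   [generateSeries()].
#' @param outCsv optional path: the corrected series is written there.
#' @return list with `series` (a [HeightSeries-class]), `detections`
#'   (per-frame run data.frame), `errors` (per-day percent errors, or
#'   `NULL`) and `summary` (`c(mean =, sd =)`, or `NULL`).
#' @export
runSeries <- function(imageDir, config, sensorCsv = NULL,
                      referenceCsv = NULL, outCsv = NULL) {
  if (!inherits(config, "PipelineConfig"))
    stopInput("'config' must be a PipelineConfig")
  if (!dir.exists(imageDir)) stopInput("image directory not found: %s", imageDir)
  files <- sort(list.files(imageDir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stopInput("no PNG/JPEG frames in %s", imageDir)
  m <- regmatches(basename(files), regexec(config$datePattern, basename(files)))
  dates <- as.Date(vapply(m, function(x)
    if (length(x) >= 2L) x[2L] else NA_character_, character(1L)))
  if (any(is.na(dates)))
    stopInput("could not parse dates from %d filename(s), e.g. %s",
              sum(is.na(dates)), basename(files[which(is.na(dates))[1L]]))
  ord <- order(dates)
  files <- files[ord]; dates <- dates[ord]
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    rows[[i]] <- tryCatch(estimateFrame(files[i], config), error = function(e) {
      warning(sprintf("frame %s: %s", basename(files[i]), conditionMessage(e)),
              call. = FALSE)
      data.frame(estimated_cm = NA_real_, detected_px = NA_real_,
                 column = NA_integer_, top = NA_integer_, bottom = NA_integer_)
    })
  }
  det <- cbind(date = dates, do.call(rbind, rows))
  if (all(is.na(det$estimated_cm)))
    stopInput("no frame in %s produced a detection", imageDir)
  light <- rain <- rep(NA_real_, length(files))
  condition <- rep("normal", length(files))
  if (!is.null(sensorCsv)) {
    sens <- utils::read.csv(sensorCsv, stringsAsFactors = FALSE)
    idx <- match(format(dates, "%Y-%m-%d"), as.character(sens$date))
    if ("light_wm2" %in% names(sens)) light <- sens$light_wm2[idx]
    if ("rain_mmh" %in% names(sens)) rain <- sens$rain_mmh[idx]
  }
  refCm <- rep(NA_real_, length(files))
  if (!is.null(referenceCsv)) {
    refDf <- utils::read.csv(referenceCsv, stringsAsFactors = FALSE)
    idx <- match(format(dates, "%Y-%m-%d"), as.character(refDf$date))
    refCm <- refDf$reference_cm[idx]
    if ("condition" %in% names(refDf)) {
      known <- !is.na(idx) & !is.na(refDf$condition[idx])
      condition[known] <- refDf$condition[idx][known]
    }
  }
  series <- heightSeries(date = dates, estimatedCm = det$estimated_cm,
                         referenceCm = refCm, condition = condition,
                         lightWm2 = light, rainMmh = rain,
                         reference = config$reference)
  rec <- records(series)
  hasSensors <- any(!is.na(rec$rain_mmh))
  rec$flagged <- vapply(seq_len(nrow(rec)), function(i) {
    if (is.na(rec$estimated_cm[i])) return(TRUE)  # failed detection
    if (hasSensors && !is.na(rec$rain_mmh[i]))
      return(flagUnreliable(rec[i, ], config$feature))
    if (config$feature == "red_band" && rec$condition[i] == "darkness")
      return(TRUE)
    rec$condition[i] == "rainfall"
  }, logical(1L))
  series <- initialize(series, records = rec)
  if (config$interpolation != "none" && any(rec$flagged) && !all(rec$flagged))
    series <- interpolateFlagged(series, config$interpolation)
  errors <- summary <- NULL
  rec <- records(series)
  usable <- !is.na(rec$reference_cm) & !is.na(rec$corrected_cm)
  if (any(usable)) {
    errors <- relativeError(rec$corrected_cm[usable], rec$reference_cm[usable])
    names(errors) <- format(rec$date[usable])
    summary <- summarizeErrors(errors)
  }
  if (!is.null(outCsv)) writeHeightSeries(series, outCsv)
  list(series = series, detections = det, errors = errors, summary = summary)
}

#' Evaluate a corrected series against reference heights
#'
#' Relative error per day (corrected estimate vs reference) plus the
#' mean/sd summary; days without a reference are skipped.
#'
#' @param series a [HeightSeries-class] with `reference_cm` filled.
#' @return list with `errors` (named percent vector) and `summary`
#'   (`c(mean =, sd =)`).
#' @export
evaluateSeries <- function(series) {
  rec <- records(series)
  usable <- !is.na(rec$reference_cm) & !is.na(rec$corrected_cm)
  if (!any(usable))
    stopInput("series has no records with both a reference and an estimate")
  errors <- relativeError(rec$corrected_cm[usable], rec$reference_cm[usable])
  names(errors) <- format(rec$date[usable])
  list(errors = errors, summary = summarizeErrors(errors))
}
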