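#' Construct a threshold model
#'
#' @param threshold clip level in filter-response units; default 2000, the
#'   value calibrated for the excess-green + marker-kernel pipeline on
#'   720x480 field frames.
#' @param provenance `"fixed"` or `"learned"`.
#' @return a [ThresholdModel-class].
#' @export
thresholdModel <- function(threshold = 2000, provenance = "fixed") {
  assertScalarNumber(threshold, "threshold")
  new("ThresholdModel", threshold = threshold, provenance = provenance)
}

#' @describeIn thresholdModel the clip level.
#' @param model a `ThresholdModel`.
#' @export
thresholdValue <- function(model) {
  if (!is(model, "ThresholdModel")) stopInput("'model' must be a ThresholdModel")
  model@threshold
}

#' @describeIn thresholdModel `"fixed"` or `"learned"`.
#' @export
thresholdProvenance <- function(model) {
  if (!is(model, "ThresholdModel")) stopInput("'model' must be a ThresholdModel")
  model@provenance
}

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf("ThresholdModel: threshold %g (%s)\n",
              object@threshold, object@provenance))
})

#' Threshold a response plane into a binary mask
#'
#' A pixel becomes 1 iff its response strictly exceeds the threshold;
#' values equal to the threshold map to 0. Mask pixels are marker-bar
#' candidates; everything else is background.
#'
#' @param plane numeric matrix of filter responses.
#' @param model a [ThresholdModel-class] or a single number.
#' @return integer matrix of 0/1, same dimensions as `plane`.
#' @export
applyThreshold <- function(plane, model = thresholdModel()) {
  assertPlane(plane)
  thr <- if (is(model, "ThresholdModel")) model@threshold
         else assertScalarNumber(model, "model")
  mask <- matrix(0L, nrow(plane), ncol(plane))
  mask[plane > thr] <- 1L
  mask
}

#' Learn a threshold from labelled response samples
#'
#' Formalises the calibration step of sampling filter responses on the
#' marker bar and on other areas (sky, trees, crop): when the two groups
#' separate cleanly, the threshold is the midpoint of the gap between the
#' largest background response and the smallest marker response, which
#' classifies every training sample correctly.
#'
#' @param markerSamples,otherSamples non-empty numeric vectors of filter
#'   responses sampled on the marker bar and elsewhere.
#' @return a [ThresholdModel-class] with provenance `"learned"`.
#' @examples
#' thresholdValue(selectThreshold(c(2500, 3000), c(100, 900)))  # 1700
#' @export
selectThreshold <- function(markerSamples, otherSamples) {
  for (s in list(marker = markerSamples, other = otherSamples))
    if (!is.numeric(s) || length(s) == 0L || any(!is.finite(s)))
      stopInput("sample lists must be non-empty finite numeric vectors")
  lo <- max(otherSamples)
  hi <- min(markerSamples)
  if (lo >= hi)
    stopSeparation(
      "marker and background responses overlap: max(other) = %g >= min(marker) = %g",
      lo, hi)
  thresholdModel((lo + hi) / 2, provenance = "learned")
}

#' Write a binary mask as PNG or plain-text PGM
#'
#' Mask values 0/1 are exported as 0/255.
#'
#' @param mask integer 0/1 matrix.
#' @param path output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stopInput("'mask' must be a 0/1 matrix")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(mask * 1.0, path)
  else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "255"), con)
    apply(mask * 255L, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  } else stopInput("unsupported mask format '.%s' (use png or pgm)", ext)
  invisible(path)
}
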