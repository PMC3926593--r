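# Internal helpers: classed conditions and small assertions.
#
# Every user-facing failure carries a condition class so callers (and the
# command-line driver) can distinguish bad inputs from genuine detection
# failures without string-matching messages.

stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "cropheight_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopInput <- function(fmt, ...) stopWithClass("cropheight_input_error", fmt, ...)
stopDetection <- function(fmt, ...) stopWithClass("cropheight_detection_error", fmt, ...)
stopSeparation <- function(fmt, ...) stopWithClass("cropheight_separation_error", fmt, ...)
stopCalibration <- function(fmt, ...) stopWithClass("cropheight_calibration_error", fmt, ...)
stopCorrection <- function(fmt, ...) stopWithClass("cropheight_correction_error", fmt, ...)

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopInput("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stopInput("'%s' must be positive (got %g)", name, x)
  invisible(x)
}

assertPlane <- function(x, name = "plane") {
  if (!is.matrix(x) || !is.numeric(x))
    stopInput("'%s' must be a numeric matrix", name)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stopInput("'%s' must have positive dimensions", name)
  if (any(!is.finite(x)))
    stopInput("'%s' contains non-finite values", name)
  invisible(x)
}

# Round half away from zero (base round() rounds half to even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
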