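#' Construct a marker-bar calibration reference
#'
#' The deployed bar is `totalCm` long with `totalCm / stripeCm` alternating
#' stripes and is driven `buriedCm` into the soil, leaving
#' `totalCm - buriedCm` above ground (the default 250 cm bar buried 20 cm
#' leaves 230 cm). `initialPx` is measured once on the calibration frame
#' (the visible bar length in pixels) and `initialCm` is the matching
#' length in cm -- by default the full above-ground length, reduced later
#' by [adjustReferenceForSky()] if top stripes merge with the sky.
#'
#' @param initialPx visible marker length on the calibration frame, pixels.
#' @param initialCm matching length in cm (default: above-ground length).
#' @param initialCropCm crop height on the calibration frame, cm.
#' @param totalCm,buriedCm,stripeCm bar geometry, cm.
#' @param markerWidthPx apparent bar width, pixels.
#' @return a [MarkerReference-class].
#' @examples
#' ref <- markerReference(initialPx = 200, initialCropCm = 77)
#' aboveGroundCm(ref)  # 230
#' @export
markerReference <- function(initialPx, initialCm = totalCm - buriedCm,
                            initialCropCm = 0, totalCm = 250, buriedCm = 20,
                            stripeCm = 10, markerWidthPx = 5) {
  new("MarkerReference", initialPx = initialPx, initialCm = initialCm,
      initialCropCm = initialCropCm, aboveGroundCm = totalCm - buriedCm,
      stripeCm = stripeCm, markerWidthPx = markerWidthPx)
}

#' @describeIn markerReference calibration length in pixels.
#' @param ref a `MarkerReference`.
#' @export
initialPx <- function(ref) ref@initialPx

#' @describeIn markerReference calibration length in cm.
#' @export
initialCm <- function(ref) ref@initialCm

#' @describeIn markerReference crop height on the calibration frame, cm.
#' @export
initialCropCm <- function(ref) ref@initialCropCm

#' @describeIn markerReference above-ground bar length, cm.
#' @export
aboveGroundCm <- function(ref) ref@aboveGroundCm

#' @describeIn markerReference stripe pitch, cm.
#' @export
stripeCm <- function(ref) ref@stripeCm

setMethod("show", "MarkerReference", function(object) {
  cat(sprintf(
    "MarkerReference: %g px = %g cm visible at calibration (crop %g cm);\n  above ground %g cm, stripe %g cm, bar width %g px\n",
    object@initialPx, object@initialCm, object@initialCropCm,
    object@aboveGroundCm, object@stripeCm, object@markerWidthPx))
})

#' Longest vertical runs of mask pixels
#'
#' Scans every column of the mask for maximal contiguous runs of 1-pixels
#' (no gap bridging) and returns the `n` longest, sorted by length
#' descending with ties broken by smaller column, then smaller top row.
#' The longest run is taken as the visible marker bar; with several bars
#' in the field, `n` can be raised to retrieve one run per bar.
#'
#' @param mask integer 0/1 matrix.
#' @param roi optional region of interest `c(x0, y0, width, height)`
#'   (1-based, x = column) applied before detection; returned coordinates
#'   stay in the full-mask frame.
#' @param n number of runs to return.
#' @return data.frame with columns `column`, `top`, `bottom`, `length`
#'   (rows/columns 1-based, `top`/`bottom` inclusive).
#' @export
longestVerticalRuns <- function(mask, roi = NULL, n = 1) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stopInput("'mask' must be a 0/1 matrix")
  if (n < 1) stopInput("'n' must be >= 1")
  x0 <- 1L; y0 <- 1L
  sub <- mask
  if (!is.null(roi)) {
    if (length(roi) != 4L || any(roi < 1))
      stopInput("'roi' must be c(x0, y0, width, height) with positive entries")
    x0 <- as.integer(roi[1L]); y0 <- as.integer(roi[2L])
    x1 <- min(ncol(mask), x0 + as.integer(roi[3L]) - 1L)
    y1 <- min(nrow(mask), y0 + as.integer(roi[4L]) - 1L)
    if (x0 > ncol(mask) || y0 > nrow(mask))
      stopInput("roi lies outside the mask")
    sub <- mask[y0:y1, x0:x1, drop = FALSE]
  }
  runs <- list()
  for (j in seq_len(ncol(sub))) {
    r <- rle(sub[, j] == 1L)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    runs[[length(runs) + 1L]] <- data.frame(
      column = x0 + j - 1L,
      top = y0 + starts[keep] - 1L,
      bottom = y0 + ends[keep] - 1L,
      length = r$lengths[keep])
  }
  if (length(runs) == 0L)
    stopDetection("no marker candidate: mask has no 1-pixels in the region of interest")
  all <- do.call(rbind, runs)
  ord <- order(-all$length, all$column, all$top)
  out <- all[ord, , drop = FALSE][seq_len(min(n, nrow(all))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert detected marker length to crop height
#'
#' The crop hides the bottom of the bar, so the hidden fraction of the
#' calibration length, plus the crop height at calibration, gives the
#' current height:
#' \deqn{H = \frac{I - M}{I} L + R}
#' with `I` the calibration marker length in pixels, `L` the same length
#' in cm, `M` the detected marker length in pixels and `R` the calibration
#' crop height in cm. `H` decreases strictly in `M`, from `L + R` at
#' `M = 0` (bar fully hidden) to `R` at `M = I` (no growth).
#'
#' @param ref a [MarkerReference-class].
#' @param detectedPx detected visible marker length `M`, pixels, in
#'   `[0, initialPx(ref)]`.
#' @return crop height in cm.
#' @examples
#' ref <- markerReference(initialPx = 200, initialCm = 220, initialCropCm = 77)
#' computeHeight(ref, 150)  # 132
#' @export
computeHeight <- function(ref, detectedPx) {
  if (!is(ref, "MarkerReference")) stopInput("'ref' must be a MarkerReference")
  assertScalarNumber(detectedPx, "detectedPx")
  if (detectedPx < 0)
    stopInput("'detectedPx' must be non-negative")
  if (detectedPx > ref@initialPx)
    stopCalibration(
      "detected marker (%g px) longer than the calibration marker (%g px): mis-detection",
      detectedPx, ref@initialPx)
  (ref@initialPx - detectedPx) / ref@initialPx * ref@initialCm + ref@initialCropCm
}

#' Trim sky-confused top stripes off the calibration reference
#'
#' When the topmost (white) stripes cannot be separated from a bright sky,
#' the calibration region is shortened by whole stripes: `initialCm` drops
#' by `cutStripes * stripeCm` and `initialPx` shrinks proportionally
#' (rounded to the nearest pixel, halves away from zero), preserving the
#' cm-per-pixel ratio within rounding.
#'
#' @param ref a [MarkerReference-class].
#' @param cutStripes number of stripes to exclude (>= 0).
#' @return an adjusted [MarkerReference-class].
#' @export
adjustReferenceForSky <- function(ref, cutStripes) {
  if (!is(ref, "MarkerReference")) stopInput("'ref' must be a MarkerReference")
  assertScalarNumber(cutStripes, "cutStripes")
  if (cutStripes < 0 || cutStripes != as.integer(cutStripes))
    stopInput("'cutStripes' must be a non-negative integer")
  if (cutStripes == 0) return(ref)
  cutCm <- cutStripes * ref@stripeCm
  if (cutCm >= ref@initialCm)
    stopInput("cutting %g stripes removes the whole %g cm calibration region",
              cutStripes, ref@initialCm)
  newCm <- ref@initialCm - cutCm
  newPx <- roundHalfAway(ref@initialPx * newCm / ref@initialCm)
  new("MarkerReference", initialPx = newPx, initialCm = newCm,
      initialCropCm = ref@initialCropCm, aboveGroundCm = ref@aboveGroundCm,
      stripeCm = ref@stripeCm, markerWidthPx = ref@markerWidthPx)
}
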