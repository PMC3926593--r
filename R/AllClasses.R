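#' @import methods
NULL

#' RGB field frame
#'
#' A thin container for a 24-bit RGB frame: a `height x width x 3` numeric
#' array on the 0--255 intensity scale (band order red, green, blue). Rows
#' run downward (y), columns rightward (x); indexing is 1-based throughout
#' the package. Derived single-band planes (channels, excess indices,
#' filter responses) are plain numeric matrices with the same row/column
#' convention.
#'
#' @slot data numeric array `[y, x, 3]`, values in `[0, 255]`.
#' @seealso [rgbImage()], [splitBands()], [excessIndex()]
#' @export
setClass("RGBImage", representation(data = "array"), validity = function(object) {
  d <- object@data
  if (length(dim(d)) != 3L || dim(d)[3L] != 3L)
    return("data must be a height x width x 3 array")
  if (dim(d)[1L] < 1L || dim(d)[2L] < 1L)
    return("image dimensions must be positive")
  if (any(!is.finite(d)))
    return("image contains non-finite values")
  if (min(d) < 0 || max(d) > 255)
    return("intensities must lie in [0, 255]")
  TRUE
})

#' Threshold model for mask segmentation
#'
#' Holds the clip level applied to a filter-response plane, together with
#' its provenance: `"fixed"` for a hand-set value (the shipped default is
#' 2000, in filter-response units of the excess-green + marker-kernel
#' pipeline) or `"learned"` when derived from labelled response samples by
#' [selectThreshold()].
#'
#' @slot threshold single finite numeric, filter-response units.
#' @slot provenance `"fixed"` or `"learned"`.
#' @seealso [thresholdModel()], [applyThreshold()]
#' @export
setClass("ThresholdModel",
  representation(threshold = "numeric", provenance = "character"),
  validity = function(object) {
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
      return("threshold must be a single finite number")
    if (!object@provenance %in% c("fixed", "learned"))
      return("provenance must be 'fixed' or 'learned'")
    TRUE
  })

#' Marker-bar calibration reference
#'
#' Geometry of the striped reference bar and of the initial (calibration)
#' frame. `initialPx` is the visible marker length in pixels on the first
#' frame, `initialCm` the corresponding length in centimetres, and
#' `initialCropCm` the crop height on that frame; these three drive the
#' pixel-to-centimetre height conversion in [computeHeight()].
#' `aboveGroundCm` is the bar's total length minus the buried part and
#' bounds what can ever be visible; `stripeCm` is the stripe pitch used
#' when trimming sky-confused top stripes ([adjustReferenceForSky()]).
#'
#' @slot initialPx visible marker length on the calibration frame, pixels.
#' @slot initialCm same length in cm.
#' @slot initialCropCm crop height on the calibration frame, cm.
#' @slot aboveGroundCm above-ground bar length, cm.
#' @slot stripeCm stripe pitch, cm.
#' @slot markerWidthPx apparent bar width in the image, pixels.
#' @seealso [markerReference()], [computeHeight()]
#' @export
setClass("MarkerReference",
  representation(initialPx = "numeric", initialCm = "numeric",
                 initialCropCm = "numeric", aboveGroundCm = "numeric",
                 stripeCm = "numeric", markerWidthPx = "numeric"),
  validity = function(object) {
    n <- c(initialPx = object@initialPx, initialCm = object@initialCm,
           initialCropCm = object@initialCropCm,
           aboveGroundCm = object@aboveGroundCm, stripeCm = object@stripeCm,
           markerWidthPx = object@markerWidthPx)
    if (any(lengths(list(object@initialPx, object@initialCm,
                         object@initialCropCm, object@aboveGroundCm,
                         object@stripeCm, object@markerWidthPx)) != 1L))
      return("all slots must be scalars")
    if (any(!is.finite(n))) return("all slots must be finite")
    if (object@initialPx <= 0) return("initialPx must be positive")
    if (object@initialCm <= 0) return("initialCm must be positive")
    if (object@initialCropCm < 0) return("initialCropCm must be non-negative")
    if (object@aboveGroundCm <= 0) return("aboveGroundCm must be positive")
    if (object@stripeCm <= 0) return("stripeCm must be positive")
    if (object@markerWidthPx < 1) return("markerWidthPx must be >= 1")
    TRUE
  })

seriesConditions <- c("normal", "darkness", "brightness", "drizzle", "rainfall")

seriesColumns <- c("date", "estimated_cm", "reference_cm", "condition",
                   "light_wm2", "rain_mmh", "flagged", "corrected_cm",
                   "correction")

#' Daily crop-height series
#'
#' An ordered set of daily records, one per frame: the estimated height,
#' an optional manual reference height, the field condition (one of
#' normal, darkness, brightness, drizzle, rainfall), optional pyranometer
#' and rain-gauge readings, a reliability flag, and -- after
#' [interpolateFlagged()] -- the corrected height and the correction
#' provenance. Dates must be strictly increasing.
#'
#' @slot records data.frame with columns `date`, `estimated_cm`,
#'   `reference_cm`, `condition`, `light_wm2`, `rain_mmh`, `flagged`,
#'   `corrected_cm`, `correction`.
#' @slot reference the [MarkerReference-class] used, or a zero-length
#'   placeholder when unknown.
#' @seealso [heightSeries()], [flagSeries()], [interpolateFlagged()]
#' @export
setClass("HeightSeries",
  representation(records = "data.frame", reference = "list"),
  validity = function(object) {
    rec <- object@records
    missing <- setdiff(seriesColumns, names(rec))
    if (length(missing))
      return(paste("records is missing columns:", paste(missing, collapse = ", ")))
    if (!inherits(rec$date, "Date")) return("date column must be of class Date")
    if (nrow(rec) > 1L && any(diff(as.numeric(rec$date)) <= 0))
      return("dates must be strictly increasing")
    est <- rec$estimated_cm
    if (any(!is.na(est) & est < 0)) return("estimated_cm must be non-negative")
    bad <- !rec$condition %in% seriesConditions
    if (any(bad))
      return(paste("unknown condition:", paste(unique(rec$condition[bad]), collapse = ", ")))
    if (!is.logical(rec$flagged)) return("flagged must be logical")
    TRUE
  })

#' Synthetic field scene specification
#'
#' Parameters of one rendered frame: canvas size, marker geometry and
#' placement, true crop height, canopy colour phase (green or gold),
#' weather condition, and the seed that fixes all randomness. The rendered
#' scene is a sky band above a vegetation canopy, with the striped bar
#' drawn over the canopy and its bottom part occluded up to the true crop
#' height; see [renderScene()] for the condition transforms.
#'
#' @slot width,height canvas size, pixels.
#' @slot cmPerPx centimetres imaged per pixel along the bar.
#' @slot totalCm,buriedCm,stripeCm bar length, buried length and stripe
#'   pitch, cm.
#' @slot markerWidthPx apparent bar width, pixels (odd).
#' @slot markerColumn centre column of the bar (NA = canvas centre).
#' @slot cropHeightCm true crop height, cm.
#' @slot canopy `"green"` or `"gold"`.
#' @slot condition one of normal, darkness, brightness, drizzle, rainfall.
#' @slot canopySd per-pixel canopy colour jitter, intensity units.
#' @slot skyFraction fraction of rows occupied by sky at the top.
#' @slot seed integer seed fixing all randomness.
#' @seealso [sceneSpec()], [renderScene()], [generateSeries()]
#' @export
setClass("SceneSpec",
  representation(width = "numeric", height = "numeric", cmPerPx = "numeric",
                 totalCm = "numeric", buriedCm = "numeric", stripeCm = "numeric",
                 markerWidthPx = "numeric", markerColumn = "numeric",
                 cropHeightCm = "numeric", canopy = "character",
                 condition = "character", canopySd = "numeric",
                 skyFraction = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@width < 32 || object@height < 32)
      return("canvas must be at least 32 x 32 pixels")
    if (object@cmPerPx <= 0) return("cmPerPx must be positive")
    if (object@buriedCm < 0 || object@buriedCm >= object@totalCm)
      return("buriedCm must lie in [0, totalCm)")
    if (object@stripeCm <= 0) return("stripeCm must be positive")
    w <- object@markerWidthPx
    if (w < 3 || w %% 2 != 1) return("markerWidthPx must be odd and >= 3")
    if (!object@canopy %in% c("green", "gold"))
      return("canopy must be 'green' or 'gold'")
    if (!object@condition %in% seriesConditions)
      return(paste("condition must be one of:", paste(seriesConditions, collapse = ", ")))
    if (object@cropHeightCm < 0) return("cropHeightCm must be non-negative")
    above <- object@totalCm - object@buriedCm
    if (object@cropHeightCm > above + object@stripeCm)
      return("cropHeightCm exceeds the above-ground bar length")
    if (object@skyFraction < 0 || object@skyFraction > 0.5)
      return("skyFraction must lie in [0, 0.5]")
    abovePx <- round(above / object@cmPerPx)
    if (abovePx + ceiling(object@skyFraction * object@height) + 8 > object@height)
      return("marker taller than the canvas allows (increase height or cmPerPx)")
    TRUE
  })
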