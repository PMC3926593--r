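# Synthetic field scenes with known ground truth.
#
# Scene palette, 0-255 per band. The colours are chosen so that the
# planes behave like the field frames: red stripes bright in the red
# band and strongly negative in excess green, white stripes bright in
# every band and excess-green-neutral, vegetation high in excess green,
# sky near excess-green zero.
scenePalette <- list(
  sky = c(185, 205, 230),
  canopyGreen = c(40, 170, 60),
  canopyGold = c(190, 160, 70),
  stripeRed = c(180, 60, 60),
  stripeWhite = c(250, 250, 250))

# Condition transforms. Darkness is a dimmer, bluer illuminant: per-band
# scales with r + b = 2g, so white surfaces stay excess-green-neutral and
# the canopy's excess-green contrast survives, while the red band's
# marker-vs-canopy contrast collapses -- the asymmetry seen in the field.
# Brightness is a uniform gain (clipped at 255). Drizzle adds mild blur,
# rainfall strong blur plus heavy sensor noise.
sceneConditions <- list(
  normal = list(scale = c(1, 1, 1), blur = 0L, noiseSd = 2),
  darkness = list(scale = c(0.45, 0.65, 0.85), blur = 0L, noiseSd = 6),
  brightness = list(scale = c(1.35, 1.35, 1.35), blur = 0L, noiseSd = 3),
  drizzle = list(scale = c(1, 1, 1), blur = 3L, noiseSd = 4),
  rainfall = list(scale = c(1, 1, 1), blur = 7L, noiseSd = 15))

#' Specify a synthetic field scene
#'
#' Defaults mirror the deployed setup scaled to a compact canvas: a
#' 250 cm bar with 10 cm stripes buried 20 cm (230 cm above ground),
#' 5 pixels wide, imaged at 1 cm per pixel on a 240 x 320 canvas with a
#' sky band over a green canopy, initial crop height 77 cm, normal
#' weather.
#'
#' @param width,height canvas size, pixels.
#' @param cmPerPx centimetres per pixel along the bar.
#' @param totalCm,buriedCm,stripeCm bar geometry, cm.
#' @param markerWidthPx apparent bar width, pixels (odd).
#' @param markerColumn centre column of the bar (default: canvas centre).
#' @param cropHeightCm true crop height, cm.
#' @param canopy `"green"` or `"gold"`.
#' @param condition one of normal, darkness, brightness, drizzle,
#'   rainfall.
#' @param canopySd per-pixel canopy colour jitter sd, intensity units.
#' @param skyFraction fraction of rows occupied by sky.
#' @param seed integer; fixes all randomness of the render.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(width = 240, height = 320, cmPerPx = 1,
                      totalCm = 250, buriedCm = 20, stripeCm = 10,
                      markerWidthPx = 5, markerColumn = NA,
                      cropHeightCm = 77, canopy = "green",
                      condition = "normal", canopySd = 12,
                      skyFraction = 0.2, seed = 1) {
  if (is.na(markerColumn)) markerColumn <- round(width / 2)
  new("SceneSpec", width = width, height = height, cmPerPx = cmPerPx,
      totalCm = totalCm, buriedCm = buriedCm, stripeCm = stripeCm,
      markerWidthPx = markerWidthPx, markerColumn = markerColumn,
      cropHeightCm = cropHeightCm, canopy = canopy, condition = condition,
      canopySd = canopySd, skyFraction = skyFraction, seed = seed)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %g x %g px, %s canopy, condition %s, crop %g cm, seed %g\n",
    object@width, object@height, object@canopy, object@condition,
    object@cropHeightCm, object@seed))
})

# Geometry shared by renderScene and the truth record.
sceneGeometry <- function(spec) {
  aboveCm <- spec@totalCm - spec@buriedCm
  visibleCm <- max(0, aboveCm - spec@cropHeightCm)
  abovePx <- round(aboveCm / spec@cmPerPx)
  visiblePx <- round(visibleCm / spec@cmPerPx)
  H <- as.integer(spec@height)
  list(aboveCm = aboveCm, visibleCm = visibleCm, abovePx = abovePx,
       visiblePx = visiblePx,
       topRow = H - abovePx + 1L,            # row of the bar's top
       cropRow = H - (abovePx - visiblePx),  # lowest visible bar row
       skyRows = max(0L, floor(spec@skyFraction * H)))
}

boxKernel <- function(size) matrix(1 / size^2, size, size)

#' Render a synthetic field frame
#'
#' Composes sky, a jittered vegetation canopy, and the striped marker bar
#' with its bottom `cropHeightCm` occluded by canopy, then applies the
#' condition transform (illuminant scaling, blur, sensor noise). The same
#' spec and seed give bit-identical output.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `image` (an [RGBImage-class]) and `truth`, a list
#'   with `visible_marker_px` (`round(visibleCm / cmPerPx)`) and
#'   `crop_height_cm`.
#' @export
renderScene <- function(spec) {
  if (!is(spec, "SceneSpec")) stopInput("'spec' must be a SceneSpec")
  validObject(spec)
  g <- sceneGeometry(spec)
  H <- as.integer(spec@height); W <- as.integer(spec@width)
  cond <- sceneConditions[[spec@condition]]
  canopyBase <- if (spec@canopy == "green") scenePalette$canopyGreen
                else scenePalette$canopyGold
  img <- withr::with_seed(as.integer(spec@seed), {
    data <- array(0, dim = c(H, W, 3L))
    for (b in 1:3) {
      plane <- matrix(canopyBase[b] + stats::rnorm(H * W, 0, spec@canopySd), H, W)
      if (g$skyRows > 0L) plane[seq_len(g$skyRows), ] <- scenePalette$sky[b]
      data[, , b] <- plane
    }
    # visible part of the bar: stripe colour by height above the ground
    # line (bottom row), alternating from a red bottom stripe
    if (g$visiblePx > 0L) {
      half <- (as.integer(spec@markerWidthPx) - 1L) %/% 2L
      cols <- (spec@markerColumn - half):(spec@markerColumn + half)
      cols <- cols[cols >= 1L & cols <= W]
      rows <- g$topRow:g$cropRow
      hCm <- (H - rows + 0.5) * spec@cmPerPx
      stripeIdx <- floor(hCm / spec@stripeCm)
      for (b in 1:3) {
        stripeCol <- ifelse(stripeIdx %% 2 == 0, scenePalette$stripeRed[b],
                            scenePalette$stripeWhite[b])
        data[rows, cols, b] <- stripeCol
      }
    }
    # condition transform: illuminant, optics, sensor noise
    for (b in 1:3) data[, , b] <- data[, , b] * cond$scale[b]
    if (cond$blur > 0L) {
      k <- boxKernel(cond$blur)
      for (b in 1:3) data[, , b] <- convolveImage(data[, , b], k)
    }
    data <- data + stats::rnorm(length(data), 0, cond$noiseSd)
    clamp(data, 0, 255)
  })
  list(image = new("RGBImage", data = img),
       truth = list(visible_marker_px = g$visiblePx,
                    crop_height_cm = spec@cropHeightCm))
}

#' Calibration reference matching a scene specification
#'
#' The reference an operator would measure off a calibration frame of
#' this scene: visible marker pixels and centimetres at the spec's crop
#' height.
#'
#' @param spec a [SceneSpec-class] describing the calibration frame.
#' @return a [MarkerReference-class].
#' @export
sceneReference <- function(spec) {
  if (!is(spec, "SceneSpec")) stopInput("'spec' must be a SceneSpec")
  g <- sceneGeometry(spec)
  markerReference(initialPx = g$visiblePx, initialCm = g$visibleCm,
                  initialCropCm = spec@cropHeightCm, totalCm = spec@totalCm,
                  buriedCm = spec@buriedCm, stripeCm = spec@stripeCm,
                  markerWidthPx = spec@markerWidthPx)
}

#' Sample labelled filter responses from a rendered scene
#'
#' Renders the scene, computes the feature plane and the marker-kernel
#' response, and samples responses at known marker pixels (the bar's
#' centre column, away from the visible ends) and at background pixels
#' (columns at least one kernel width away from the bar). Feed the two
#' vectors to [selectThreshold()] to calibrate a threshold for this
#' deployment.
#'
#' @param spec a [SceneSpec-class].
#' @param feature `"excess_green"` or `"red_band"`.
#' @param nEach samples per class (default 200).
#' @return list with numeric vectors `marker` and `other`.
#' @export
sceneThresholdSamples <- function(spec, feature = c("excess_green", "red_band"),
                                  nEach = 200) {
  feature <- match.arg(feature)
  if (nEach < 1) stopInput("'nEach' must be >= 1")
  scene <- renderScene(spec)
  plane <- featurePlane(scene$image, feature)
  resp <- convolveImage(plane, modifiedKernel(spec@markerWidthPx))
  if (feature == "red_band") resp <- -resp
  g <- sceneGeometry(spec)
  if (g$visiblePx < 4L * spec@markerWidthPx)
    stopInput("visible marker too short to sample marker responses")
  margin <- as.integer(spec@markerWidthPx)
  markerRows <- (g$topRow + margin):(g$cropRow - margin)
  half <- (as.integer(spec@markerWidthPx) - 1L) %/% 2L
  kernelHalf <- as.integer(spec@markerWidthPx)  # kernel half-width = w
  bgCols <- setdiff(seq_len(as.integer(spec@width)),
                    (spec@markerColumn - half - 2L * kernelHalf):
                    (spec@markerColumn + half + 2L * kernelHalf))
  withr::with_seed(as.integer(spec@seed) + 1L, {
    mIdx <- sample(markerRows, nEach, replace = TRUE)
    marker <- resp[cbind(mIdx, spec@markerColumn)]
    bIdx <- cbind(sample(seq_len(nrow(resp)), nEach, replace = TRUE),
                  sample(bgCols, nEach, replace = TRUE))
    other <- resp[bIdx]
    list(marker = marker, other = other)
  })
}

#' Generate a daily frame series with ground truth
#'
#' One frame per day (seeded independently from the base seed), written
#' as PNG files named `frame_YYYY-MM-DD.png` together with `truth.csv`
#' holding the true heights in the series CSV layout, or returned
#' in memory when `dir` is `NULL`.
#'
#' @param base a [SceneSpec-class]; per-day specs vary its crop height and
#'   condition.
#' @param heights true crop heights, cm, one per day.
#' @param conditions condition labels, same length as `heights` (a single
#'   value is recycled).
#' @param dates `Date` vector (default: consecutive days from
#'   `startDate`).
#' @param startDate first day, used when `dates` is missing.
#' @param dir output directory, or `NULL` to keep frames in memory.
#' @return list with `truth` (data.frame: `date`, `reference_cm`,
#'   `condition`, `visible_marker_px`) and either `files` (written paths)
#'   or `images` (list of [RGBImage-class]).
#' @export
generateSeries <- function(base, heights, conditions = "normal",
                           dates = NULL, startDate = as.Date("2012-07-01"),
                           dir = NULL) {
  if (!is(base, "SceneSpec")) stopInput("'base' must be a SceneSpec")
  n <- length(heights)
  if (length(conditions) == 1L) conditions <- rep(conditions, n)
  if (length(conditions) != n)
    stopInput("'heights' (%d) and 'conditions' (%d) differ in length",
              n, length(conditions))
  if (is.null(dates)) dates <- startDate + seq_len(n) - 1L
  if (length(dates) != n) stopInput("'dates' must match 'heights' in length")
  truth <- data.frame(date = as.Date(dates), reference_cm = as.numeric(heights),
                      condition = as.character(conditions),
                      visible_marker_px = rep(NA_integer_, n))
  images <- vector("list", n)
  files <- character(n)
  for (i in seq_len(n)) {
    spec <- initialize(base, cropHeightCm = as.numeric(heights[i]),
                       condition = as.character(conditions[i]),
                       seed = base@seed + i)
    scene <- renderScene(spec)
    truth$visible_marker_px[i] <- scene$truth$visible_marker_px
    if (is.null(dir)) {
      images[[i]] <- scene$image
    } else {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files[i] <- file.path(dir, sprintf("frame_%s.png", format(truth$date[i])))
      writeRGBImage(scene$image, files[i])
    }
  }
  out <- list(truth = truth)
  if (is.null(dir)) {
    out$images <- images
  } else {
    out$files <- files
    truthOut <- truth
    truthOut$date <- format(truthOut$date, "%Y-%m-%d")
    utils::write.csv(truthOut, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    out$truthFile <- file.path(dir, "truth.csv")
  }
  out
}
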