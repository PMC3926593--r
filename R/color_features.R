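#' Construct an RGB frame from channel planes
#'
#' @param red,green,blue numeric matrices of equal dimensions with values
#'   in `[0, 255]` (rows = y downward, columns = x rightward).
#' @return an [RGBImage-class].
#' @examples
#' img <- rgbImage(matrix(10, 2, 2), matrix(20, 2, 2), matrix(30, 2, 2))
#' dim(img)
#' @export
rgbImage <- function(red, green, blue) {
  for (p in list(red = red, green = green, blue = blue))
    if (!is.matrix(p) || !is.numeric(p))
      stopInput("channel planes must be numeric matrices")
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stopInput("channel planes have mismatched dimensions (%dx%d, %dx%d, %dx%d)",
              nrow(red), ncol(red), nrow(green), ncol(green), nrow(blue), ncol(blue))
  data <- array(0, dim = c(nrow(red), ncol(red), 3L))
  data[, , 1L] <- red; data[, , 2L] <- green; data[, , 3L] <- blue
  new("RGBImage", data = data)
}

#' @describeIn rgbImage image dimensions as `c(height, width)`.
#' @param x an `RGBImage`.
#' @export
setMethod("dim", "RGBImage", function(x) dim(x@data)[1:2])

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("RGBImage: %d x %d pixels (height x width), 3 bands, range [%g, %g]\n",
              d[1L], d[2L], min(object@data), max(object@data)))
})

bandIndex <- function(which) {
  i <- match(match.arg(which, c("red", "green", "blue")), c("red", "green", "blue"))
  i
}

#' Split an RGB frame into its three band planes
#'
#' Returns the red, green and blue channels unchanged, as plain numeric
#' matrices on the 0--255 scale. Band selection is the pipeline's first
#' step: the red band renders both the white and the red marker stripes
#' uniformly bright, while the excess-green index renders both uniformly
#' dark against vegetation.
#'
#' @param img an [RGBImage-class].
#' @return named list with elements `red`, `green`, `blue`.
#' @export
splitBands <- function(img) {
  if (!is(img, "RGBImage")) stopInput("'img' must be an RGBImage")
  d <- dim(img@data)
  plane <- function(i) matrix(img@data[, , i], d[1L], d[2L])
  list(red = plane(1L), green = plane(2L), blue = plane(3L))
}

#' Excess-colour index plane
#'
#' Per-pixel excess index: `2X - Y - Z` where `X` is the selected band and
#' `Y`, `Z` the remaining two (excess green is `2G - R - B`). Computed in
#' signed arithmetic with no clipping or rescaling, so the output lies in
#' `[-510, 510]` for 8-bit input and is exactly 0 on achromatic pixels.
#' The three indices sum to zero at every pixel.
#'
#' @param img an [RGBImage-class].
#' @param which `"green"` (default), `"red"` or `"blue"`.
#' @return numeric matrix, same dimensions as the image.
#' @examples
#' img <- rgbImage(matrix(0), matrix(255), matrix(0))
#' excessIndex(img, "green")  # 510
#' @export
excessIndex <- function(img, which = c("green", "red", "blue")) {
  if (!is(img, "RGBImage")) stopInput("'img' must be an RGBImage")
  if (is.character(which) && length(which) == 1L &&
      !which %in% c("green", "red", "blue"))
    stopInput("unknown excess index '%s' (use 'red', 'green' or 'blue')", which)
  i <- bandIndex(which)
  others <- setdiff(1:3, i)
  d <- dim(img@data)
  matrix(2 * img@data[, , i] - img@data[, , others[1L]] - img@data[, , others[2L]],
         d[1L], d[2L])
}

#' Read an RGB frame from a JPEG or PNG file
#'
#' Decodes to the 0--255 scale with no gamma or white-balance correction.
#' Grayscale files are replicated across the three bands; an alpha channel
#' is dropped.
#'
#' @param path file path; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`).
#' @return an [RGBImage-class].
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path)) stopInput("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stopInput("unsupported image format '.%s' (use PNG or JPEG)", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  data <- raw * 255
  new("RGBImage", data = data)
}

#' Write an RGB frame as PNG
#'
#' @param img an [RGBImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(img, path) {
  if (!is(img, "RGBImage")) stopInput("'img' must be an RGBImage")
  png::writePNG(clamp(img@data, 0, 255) / 255, path)
  invisible(path)
}

#' Export a scalar plane as plain-text PGM
#'
#' Debug output for band, excess-index or filter-response planes: values
#' are affinely rescaled to 0--255 (a constant plane maps to 0) and
#' written as ASCII (P2) portable graymap, viewable in any image tool.
#'
#' @param plane numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePGM <- function(plane, path) {
  assertPlane(plane)
  rng <- range(plane)
  scaled <- if (diff(rng) == 0) matrix(0L, nrow(plane), ncol(plane))
            else matrix(as.integer(round((plane - rng[1L]) / diff(rng) * 255)),
                        nrow(plane), ncol(plane))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(plane), nrow(plane)), "255"), con)
  apply(scaled, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
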