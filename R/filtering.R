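# Convolution kernels and their application.
#
# All kernels here are zero-sum, which makes the filter response invariant
# to adding a constant to every pixel -- the property that lets a fixed
# threshold survive day-to-day illumination offsets.

assertOddKernel <- function(k) {
  if (!is.matrix(k) || !is.numeric(k))
    stopInput("kernel must be a numeric matrix")
  if (nrow(k) %% 2 != 1 || ncol(k) %% 2 != 1)
    stopInput("kernel dimensions must be odd (got %d x %d)", nrow(k), ncol(k))
  invisible(k)
}

#' Discrete Laplacian kernel
#'
#' The 3x3 second-derivative kernel (sum of the discrete second
#' differences along x and y), with the negative-centre sign convention:
#' the 4-neighbour form has centre -4 and the cross set to +1, the
#' 8-neighbour form centre -8 and all neighbours +1. Coefficients sum to
#' zero, so a constant image gives an all-zero response.
#'
#' @param neighbors 4 or 8.
#' @return 3x3 numeric matrix.
#' @export
laplacianKernel <- function(neighbors = 4) {
  if (!neighbors %in% c(4, 8))
    stopInput("'neighbors' must be 4 or 8 (got %s)", toString(neighbors))
  if (neighbors == 4)
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  else
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
}

#' Directional first-derivative kernel
#'
#' A 3x3 central-difference kernel along one axis. The x kernel has
#' columns (-1, 0, +1) replicated over its three rows and picks up sudden
#' horizontal gradients (long vertical edges, such as the sides of the
#' marker bar); the y kernel is its transpose. Zero-sum and antisymmetric
#' across the centre line orthogonal to the axis.
#'
#' @param axis `"x"` or `"y"`.
#' @return 3x3 numeric matrix.
#' @export
directionalKernel <- function(axis = c("x", "y")) {
  if (is.character(axis) && length(axis) == 1L && !axis %in% c("x", "y"))
    stopInput("unknown axis '%s' (use 'x' or 'y')", axis)
  axis <- match.arg(axis)
  kx <- matrix(rep(c(-1, 0, 1), each = 3), 3, 3)
  if (axis == "x") kx else t(kx)
}

#' Marker-matched filter kernel
#'
#' The pipeline's bespoke square kernel, sized from the marker bar's
#' apparent width `w` (pixels): side length `2w + 1`, the central `w`
#' columns one negative constant, the `(w + 1) / 2` leftmost and rightmost
#' columns one positive constant, and every entry within a column equal.
#' The constants are `+w` (flanks) and `-(w + 1)` (centre), so each row
#' sums to zero. On an excess-green plane the marker is dark and its
#' vegetated surround bright; centred on the bar the kernel multiplies
#' negative values by negative coefficients and positive by positive,
#' producing a strong positive response, while laterally uniform regions
#' (sky, canopy, horizontal boundaries) cancel to zero.
#'
#' @param markerWidthPx odd integer `>= 3`: the bar width in pixels. Width
#'   5 gives the 11x11 kernel; widths 3 and 7 give 7x7 and 15x15, the
#'   sizes appropriate after down- or up-sampling the frame.
#' @return square numeric matrix of side `2 * markerWidthPx + 1`.
#' @examples
#' dim(modifiedKernel(5))  # 11 11
#' @export
modifiedKernel <- function(markerWidthPx) {
  assertScalarNumber(markerWidthPx, "markerWidthPx")
  w <- markerWidthPx
  if (w != as.integer(w) || w < 3 || w %% 2 != 1)
    stopInput("'markerWidthPx' must be an odd integer >= 3 (got %s)", toString(w))
  w <- as.integer(w)
  s <- 2L * w + 1L
  flank <- (w + 1L) %/% 2L
  colVals <- c(rep(w, flank), rep(-(w + 1L), w), rep(w, flank))
  matrix(rep(colVals, each = s), nrow = s, ncol = s)
}

#' Spatial correlation of a plane with a kernel
#'
#' Slides the kernel over every pixel (no kernel flip; all kernels used
#' here are mirror-symmetric or thresholded on magnitude, so correlation
#' and convolution coincide observationally). The border is handled by
#' replicating the nearest edge pixel, keeping the output the same size as
#' the input so run lengths are comparable across frames.
#'
#' @param plane numeric matrix.
#' @param kernel odd-dimensioned numeric matrix, no larger than the plane.
#' @return numeric matrix, same dimensions as `plane`.
#' @export
convolveImage <- function(plane, kernel) {
  assertPlane(plane)
  assertOddKernel(kernel)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nrow(plane) || kc > ncol(plane))
    stopInput("kernel (%d x %d) is larger than the image (%d x %d)",
              kr, kc, nrow(plane), ncol(plane))
  ry <- (kr - 1L) %/% 2L
  rx <- (kc - 1L) %/% 2L
  # replicate-pad, then accumulate one shifted submatrix per coefficient
  padded <- plane[
    clamp(seq_len(nrow(plane) + 2L * ry) - ry, 1L, nrow(plane)),
    clamp(seq_len(ncol(plane) + 2L * rx) - rx, 1L, ncol(plane)),
    drop = FALSE]
  out <- matrix(0, nrow(plane), ncol(plane))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      kij <- kernel[i, j]
      if (kij == 0) next
      out <- out + kij * padded[(i - 1L) + seq_len(nrow(plane)),
                                (j - 1L) + seq_len(ncol(plane))]
    }
  }
  out
}

#' Write or read a kernel as a plain-text matrix
#'
#' Whitespace-separated rows, one per line, for inspection and for feeding
#' externally designed kernels into the pipeline.
#'
#' @param kernel numeric matrix.
#' @param path file path.
#' @return `writeKernel`: `path` invisibly; `readKernel`: numeric matrix.
#' @export
writeKernel <- function(kernel, path) {
  assertOddKernel(kernel)
  writeLines(apply(kernel, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
  if (!file.exists(path)) stopInput("kernel file not found: %s", path)
  rows <- lapply(strsplit(trimws(readLines(path)), "\\s+"), as.numeric)
  rows <- rows[lengths(rows) > 0L]
  if (length(unique(lengths(rows))) != 1L)
    stopInput("ragged kernel file: %s", path)
  k <- do.call(rbind, rows)
  assertOddKernel(k)
  k
}
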