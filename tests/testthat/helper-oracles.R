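# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (nested loops, direct formulas) so they check the
# vectorised implementations from outside.

randomRGB <- function(h, w) {
  rgbImage(matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w))
}

# correlation with replicate border, one placement at a time
bruteCorrelate <- function(plane, kernel) {
  ry <- (nrow(kernel) - 1) / 2
  rx <- (ncol(kernel) - 1) / 2
  out <- matrix(0, nrow(plane), ncol(plane))
  for (y in seq_len(nrow(plane))) for (x in seq_len(ncol(plane))) {
    acc <- 0
    for (i in seq_len(nrow(kernel))) for (j in seq_len(ncol(kernel))) {
      yy <- min(max(y + i - 1 - ry, 1), nrow(plane))
      xx <- min(max(x + j - 1 - rx, 1), ncol(plane))
      acc <- acc + kernel[i, j] * plane[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# every maximal vertical run of 1s, by walking each column pixel by pixel
bruteRuns <- function(mask) {
  runs <- NULL
  for (j in seq_len(ncol(mask))) {
    top <- NA
    for (i in seq_len(nrow(mask) + 1)) {
      on <- i <= nrow(mask) && mask[i, j] == 1
      if (on && is.na(top)) top <- i
      if (!on && !is.na(top)) {
        runs <- rbind(runs, data.frame(column = j, top = top, bottom = i - 1,
                                       length = i - top))
        top <- NA
      }
    }
  }
  runs
}

# Welch statistic straight from the formula
bruteWelch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# a calibration reference and learned thresholds shared by pipeline tests
defaultSceneRef <- function() sceneReference(sceneSpec(cropHeightCm = 0))

learnedThreshold <- function(feature, seed = 7) {
  s <- sceneThresholdSamples(sceneSpec(cropHeightCm = 77, seed = seed), feature)
  selectThreshold(s$marker, s$other)
}
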