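test_that("rendered scenes are deterministic under the seed", {
  spec <- sceneSpec(cropHeightCm = 90, condition = "drizzle", seed = 77)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(a$image@data, b$image@data)
  c <- renderScene(sceneSpec(cropHeightCm = 90, condition = "drizzle", seed = 78))
  expect_false(identical(a$image@data, c$image@data))
})

test_that("truth geometry follows the marker layout", {
  sc <- renderScene(sceneSpec(cropHeightCm = 77, cmPerPx = 1))
  expect_equal(sc$truth$visible_marker_px, 153)  # 230 - 77
  expect_equal(sc$truth$crop_height_cm, 77)
  full <- renderScene(sceneSpec(cropHeightCm = 0))
  expect_equal(full$truth$visible_marker_px, 230)  # no occlusion
  half <- renderScene(sceneSpec(cropHeightCm = 77, cmPerPx = 2, height = 160))
  expect_equal(half$truth$visible_marker_px, round(153 / 2))
})

test_that("oversized markers and bad conditions are rejected", {
  expect_error(sceneSpec(height = 100, cmPerPx = 1), "taller than the canvas")
  expect_error(sceneSpec(condition = "hail"), "condition")
  expect_error(sceneSpec(markerWidthPx = 4), "odd")
})

test_that("stripe colours have the polarity the band selection relies on", {
  spec <- sceneSpec(cropHeightCm = 60, canopySd = 0, condition = "normal", seed = 3)
  sc <- renderScene(spec)
  b <- splitBands(sc$image)
  eg <- excessIndex(sc$image, "green")
  g <- cropheight:::sceneGeometry(spec)
  col <- spec@markerColumn
  rows <- g$topRow:g$cropRow
  hCm <- (spec@height - rows + 0.5) * spec@cmPerPx
  redRows <- rows[floor(hCm / spec@stripeCm) %% 2 == 0]
  whiteRows <- rows[floor(hCm / spec@stripeCm) %% 2 == 1]
  canopyCols <- c(20, spec@width - 20)
  canopyRed <- mean(b$red[rows, canopyCols])
  # red stripes: bright in red band, strongly negative in excess green
  expect_gt(mean(b$red[redRows, col]), canopyRed + 80)
  expect_lt(mean(eg[redRows, col]), -80)
  # white stripes: bright in every band, excess-green neutral
  for (band in b) expect_gt(mean(band[whiteRows, col]), 200)
  expect_lt(abs(mean(eg[whiteRows, col])), 25)
  # canopy: high excess green
  expect_gt(mean(eg[rows, canopyCols]), 150)
})

test_that("generateSeries writes aligned frames and truth that round-trips", {
  dir <- withr::local_tempdir()
  base <- sceneSpec(seed = 5)
  res <- generateSeries(base, heights = c(77, 80, 85),
                        conditions = c("normal", "rainfall", "normal"),
                        dir = dir)
  expect_length(res$files, 3)
  expect_true(all(file.exists(res$files)))
  truth <- read.csv(res$truthFile)
  expect_equal(truth$reference_cm, c(77, 80, 85))
  expect_equal(truth$condition, c("normal", "rainfall", "normal"))
  # heights survive the series reader unchanged
  back <- readHeightSeries(res$truthFile)
  expect_equal(records(back)$reference_cm, c(77, 80, 85))
  expect_equal(records(back)$date, as.Date("2012-07-01") + 0:2)

  empty <- generateSeries(base, heights = numeric(0), conditions = character(0))
  expect_equal(nrow(empty$truth), 0)
  expect_length(empty$images, 0)
  expect_error(
    generateSeries(base, heights = c(1, 2, 3),
                   conditions = c("normal", "rainfall")),
    class = "cropheight_input_error")
})

test_that("a 48-day ramp yields one frame and truth row per day", {
  heights <- c(seq(77, 119, length.out = 22), seq(119, 100, length.out = 27)[-1])
  res <- generateSeries(sceneSpec(seed = 11), heights)
  expect_length(res$images, 48)
  expect_equal(nrow(res$truth), 48)
  expect_equal(range(res$truth$date), as.Date(c("2012-07-01", "2012-08-17")))
})

test_that("threshold samples separate marker from background on normal scenes", {
  for (feature in c("excess_green", "red_band")) {
    s <- sceneThresholdSamples(sceneSpec(cropHeightCm = 77, seed = 19), feature)
    expect_length(s$marker, 200)
    expect_length(s$other, 200)
    expect_gt(min(s$marker), max(s$other))
  }
})
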