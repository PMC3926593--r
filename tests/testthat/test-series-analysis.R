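test_that("relative error matches the worked cases and is scale-invariant", {
  expect_equal(relativeError(159.6, 117.0), 36.41, tolerance = 1e-4)
  expect_equal(relativeError(77.0, 77.0), 0)
  expect_equal(relativeError(50, 100), 50)
  set.seed(37)
  est <- runif(20, 10, 200); ref <- runif(20, 10, 200); k <- runif(1, 0.1, 9)
  expect_equal(relativeError(k * est, k * ref), relativeError(est, ref))
  expect_error(relativeError(100, 0), class = "cropheight_input_error")
})

test_that("light classes split at 400 and 1000 W/m2", {
  expect_equal(classifyLight(c(0, 399, 400, 700, 1000, 1001, 1500)),
               c("darkness", "darkness", "normal", "normal", "normal",
                 "brightness", "brightness"))
  expect_error(classifyLight(-5), class = "cropheight_input_error")
})

test_that("flagging depends on the feature mode", {
  rainy <- list(rain_mmh = 10.2, light_wm2 = 600)
  darkDry <- list(rain_mmh = 0, light_wm2 = 300)
  expect_true(flagUnreliable(rainy, "excess_green"))
  expect_false(flagUnreliable(darkDry, "excess_green"))
  expect_true(flagUnreliable(darkDry, "red_band"))
  expect_true(flagUnreliable(list(rain_mmh = 0, condition = "darkness"), "red_band"))
  expect_error(flagUnreliable(list(light_wm2 = 300), "excess_green"),
               class = "cropheight_input_error")
})

test_that("interpolation replaces flagged records per strategy", {
  s <- heightSeries(as.Date("2012-07-01") + 0:2, c(100, 115, 120),
                    flagged = c(FALSE, TRUE, FALSE))
  lin <- records(interpolateFlagged(s, "linear"))
  expect_equal(lin$corrected_cm, c(100, 110, 120))
  expect_equal(lin$correction, c("none", "linear", "none"))
  prev <- records(interpolateFlagged(s, "previous"))
  expect_equal(prev$corrected_cm, c(100, 100, 120))
  # single-neighbour rule at the boundary
  s2 <- heightSeries(as.Date("2012-07-01") + 0:1, c(130, 100),
                     flagged = c(TRUE, FALSE))
  expect_equal(records(interpolateFlagged(s2, "linear"))$corrected_cm[1], 100)
  # non-equidistant dates weight by time
  s3 <- heightSeries(as.Date(c("2012-07-01", "2012-07-02", "2012-07-04")),
                     c(100, 0, 130), flagged = c(FALSE, TRUE, FALSE))
  expect_equal(records(interpolateFlagged(s3, "linear"))$corrected_cm[2], 110)
  expect_error(interpolateFlagged(
    heightSeries(as.Date("2012-07-01"), 100, flagged = TRUE)),
    class = "cropheight_correction_error")
})

test_that("interpolation is idempotent and leaves unflagged records alone", {
  set.seed(41)
  for (strategy in c("linear", "previous")) {
    n <- 15
    flags <- rbinom(n, 1, 0.3) == 1
    flags[c(1, 8)] <- c(TRUE, FALSE)  # keep at least one of each
    s <- heightSeries(as.Date("2012-07-01") + 0:(n - 1), runif(n, 70, 130),
                      flagged = flags)
    once <- interpolateFlagged(s, strategy)
    twice <- interpolateFlagged(once, strategy)
    expect_equal(records(once), records(twice))
    rec <- records(once)
    expect_equal(rec$corrected_cm[!flags], rec$estimated_cm[!flags])
    expect_true(all(rec$correction[flags] == strategy))
  }
})

test_that("the worked rainy-day correction recovers the reported values", {
  exg <- fieldTrialErrors("excess_green")
  s <- heightSeries(exg$date, exg$estimated_cm, referenceCm = exg$reference_cm,
                    condition = exg$condition,
                    flagged = exg$condition == "rainfall")
  prev <- records(interpolateFlagged(s, "previous"))
  i <- which(prev$date == as.Date("2012-07-25"))
  expect_equal(prev$corrected_cm[i], 117.7)  # previous day's estimate
  expect_equal(relativeError(prev$corrected_cm[i], prev$reference_cm[i]),
               0.598, tolerance = 1e-3)
})

test_that("error summaries match a two-pass oracle", {
  expect_equal(summarizeErrors(c(5, 5, 5)), c(mean = 5, sd = 0))
  set.seed(43)
  for (rep in 1:5) {
    x <- runif(sample(2:60, 1), 0, 100)
    s <- summarizeErrors(x)
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(unname(s["mean"]), m, tolerance = 1e-9)
    expect_equal(unname(s["sd"]), sqrt(v), tolerance = 1e-9)
  }
  expect_error(summarizeErrors(numeric(0)), class = "cropheight_input_error")
})

test_that("Welch comparison matches the direct formula and is antisymmetric", {
  a <- c(0, 0, 10, 10); b <- c(0, 1, 0, 1)
  got <- compareFeaturesT(a, b)
  want <- bruteWelch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-9)

  swapped <- compareFeaturesT(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  x <- c(1, 2, 3, 4)
  expect_equal(compareFeaturesT(x, x)$t, 0)
  expect_error(compareFeaturesT(1, c(1, 2)), class = "cropheight_input_error")
})

test_that("series CSV I/O round-trips", {
  s <- heightSeries(as.Date("2012-07-01") + 0:3, c(77, 78.3, NA, 81),
                    referenceCm = c(77, 77, 77, 78),
                    condition = c("normal", "normal", "rainfall", "normal"),
                    lightWm2 = c(600, 700, 450, 380),
                    rainMmh = c(0, 0, 10.2, 0))
  s <- interpolateFlagged(s, "linear")
  path <- withr::local_tempfile(fileext = ".csv")
  writeHeightSeries(s, path)
  back <- readHeightSeries(path)
  expect_equal(records(back), records(s), tolerance = 1e-9)
})

test_that("sensor readings override light-related condition labels", {
  s <- heightSeries(as.Date("2012-07-01") + 0:1, c(80, 81),
                    condition = c("normal", "rainfall"),
                    lightWm2 = c(300, 500), rainMmh = c(0, 12))
  rec <- records(s)
  expect_equal(rec$condition, c("darkness", "rainfall"))
  expect_equal(rec$flagged, c(FALSE, TRUE))
})

test_that("bundled field-trial tables load with the full season", {
  for (f in c("excess_green", "red_band")) {
    df <- fieldTrialErrors(f)
    expect_equal(nrow(df), 48)
    expect_equal(range(df$date), as.Date(c("2012-07-01", "2012-08-17")))
    expect_true(all(df$condition %in%
                      c("normal", "darkness", "brightness", "drizzle", "rainfall")))
    # error column is consistent with the heights, within their 0.1 cm
    # print precision (~0.13 percentage points at 77 cm)
    recomputed <- relativeError(df$estimated_cm, df$reference_cm)
    expect_lt(max(abs(recomputed - df$relative_error_pct)), 0.3)
  }
})
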