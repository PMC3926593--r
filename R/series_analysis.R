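#' Relative error between estimated and reference heights
#'
#' `|estimated - reference| / reference * 100`, the series' accuracy
#' metric. Vectorised; scale-invariant in its two arguments.
#'
#' @param estimatedCm,referenceCm heights in cm; `referenceCm` must be
#'   positive.
#' @return percent error(s).
#' @examples
#' relativeError(159.6, 117.0)  # 36.41
#' @export
relativeError <- function(estimatedCm, referenceCm) {
  if (!is.numeric(estimatedCm) || !is.numeric(referenceCm))
    stopInput("heights must be numeric")
  if (any(!is.finite(referenceCm)) || any(referenceCm <= 0))
    stopInput("'referenceCm' must be positive and finite")
  abs(estimatedCm - referenceCm) / referenceCm * 100
}

#' Classify light intensity from a pyranometer reading
#'
#' Irradiance below 400 W/m2 is darkness, above 1000 W/m2 brightness;
#' 400--1000 inclusive is normal.
#'
#' @param lightWm2 non-negative irradiance(s), W/m2.
#' @return character vector of `"darkness"`, `"normal"`, `"brightness"`.
#' @export
classifyLight <- function(lightWm2) {
  if (!is.numeric(lightWm2) || any(!is.finite(lightWm2)))
    stopInput("'lightWm2' must be finite numeric")
  if (any(lightWm2 < 0)) stopInput("'lightWm2' must be non-negative")
  ifelse(lightWm2 < 400, "darkness",
         ifelse(lightWm2 > 1000, "brightness", "normal"))
}

#' Flag a record as unreliable from sensor logs
#'
#' In `excess_green` mode a record is unreliable when the rain gauge shows
#' any rain at capture time (rain blurs the frame and truncates the
#' segmented marker). In `red_band` mode low light also makes the
#' segmentation fail, so darkness records are flagged as well; darkness is
#' read from the pyranometer when a reading is present, otherwise from the
#' condition label.
#'
#' @param record a list or one-row data.frame with `rain_mmh` and, for
#'   `red_band` mode, `light_wm2` or `condition`.
#' @param mode `"excess_green"` or `"red_band"`.
#' @return logical.
#' @export
flagUnreliable <- function(record, mode = c("excess_green", "red_band")) {
  mode <- match.arg(mode)
  rain <- record[["rain_mmh"]]
  if (is.null(rain) || length(rain) != 1L || is.na(rain))
    stopInput("record needs a 'rain_mmh' value for flagging")
  flagged <- rain > 0
  if (mode == "red_band") {
    light <- record[["light_wm2"]]
    if (!is.null(light) && length(light) == 1L && !is.na(light)) {
      flagged <- flagged || classifyLight(light) == "darkness"
    } else if (!is.null(record[["condition"]]) && !is.na(record[["condition"]])) {
      flagged <- flagged || record[["condition"]] == "darkness"
    } else {
      stopInput("red_band flagging needs 'light_wm2' or a condition label")
    }
  }
  flagged
}

#' Assemble a daily height series
#'
#' @param date `Date` vector (strictly increasing).
#' @param estimatedCm estimated heights, cm.
#' @param referenceCm optional manual reference heights, cm.
#' @param condition condition labels (normal, darkness, brightness,
#'   drizzle, rainfall); when pyranometer readings are supplied they
#'   override any light-related label.
#' @param lightWm2,rainMmh optional sensor readings.
#' @param flagged optional logical reliability flags; when missing and
#'   sensor data exist, flags come from [flagUnreliable()] in
#'   `excess_green` mode.
#' @param reference optional [MarkerReference-class] used for the
#'   estimates.
#' @return a [HeightSeries-class].
#' @export
heightSeries <- function(date, estimatedCm, referenceCm = NA_real_,
                         condition = "normal", lightWm2 = NA_real_,
                         rainMmh = NA_real_, flagged = NULL,
                         reference = NULL) {
  date <- as.Date(date)
  n <- length(date)
  rec <- data.frame(
    date = date,
    estimated_cm = rep_len(as.numeric(estimatedCm), n),
    reference_cm = rep_len(as.numeric(referenceCm), n),
    condition = rep_len(as.character(condition), n),
    light_wm2 = rep_len(as.numeric(lightWm2), n),
    rain_mmh = rep_len(as.numeric(rainMmh), n),
    stringsAsFactors = FALSE)
  hasLight <- !is.na(rec$light_wm2)
  rec$condition[hasLight & !rec$condition %in% c("drizzle", "rainfall")] <-
    classifyLight(rec$light_wm2[hasLight & !rec$condition %in% c("drizzle", "rainfall")])
  if (is.null(flagged)) {
    flagged <- !is.na(rec$rain_mmh) & rec$rain_mmh > 0
  }
  rec$flagged <- rep_len(as.logical(flagged), n)
  rec$corrected_cm <- rec$estimated_cm
  rec$correction <- rep_len("none", n)
  new("HeightSeries", records = rec,
      reference = if (is.null(reference)) list() else list(reference))
}

#' @describeIn heightSeries the per-day records as a data.frame.
#' @param series a `HeightSeries`.
#' @export
records <- function(series) {
  if (!is(series, "HeightSeries")) stopInput("'series' must be a HeightSeries")
  series@records
}

#' @describeIn heightSeries the [MarkerReference-class] used, or `NULL`.
#' @export
seriesReference <- function(series) {
  if (!is(series, "HeightSeries")) stopInput("'series' must be a HeightSeries")
  if (length(series@reference)) series@reference[[1L]] else NULL
}

setMethod("show", "HeightSeries", function(object) {
  rec <- object@records
  cat(sprintf("HeightSeries: %d daily records, %s to %s\n", nrow(rec),
              min(rec$date), max(rec$date)))
  cat(sprintf("  flagged: %d; conditions: %s\n", sum(rec$flagged),
              paste(sprintf("%s=%d", names(table(rec$condition)),
                            table(rec$condition)), collapse = ", ")))
})

setMethod("length", "HeightSeries", function(x) nrow(x@records))

#' Re-flag a series from its sensor columns
#'
#' Applies [flagUnreliable()] row-wise with the given feature mode and
#' returns the series with updated flags (corrections are reset).
#'
#' @param series a [HeightSeries-class] with sensor columns filled.
#' @param mode `"excess_green"` or `"red_band"`.
#' @return a [HeightSeries-class].
#' @export
flagSeries <- function(series, mode = c("excess_green", "red_band")) {
  mode <- match.arg(mode)
  rec <- records(series)
  rec$flagged <- vapply(seq_len(nrow(rec)), function(i)
    flagUnreliable(rec[i, ], mode), logical(1L))
  rec$corrected_cm <- rec$estimated_cm
  rec$correction <- "none"
  initialize(series, records = rec)
}

#' Replace flagged estimates by interpolation from reliable days
#'
#' The hybrid correction: estimates from rain- or darkness-degraded
#' frames are replaced using reliable neighbouring days. `"linear"`
#' interpolates between the nearest unflagged neighbours, weighted by
#' date (a flagged day at the series edge takes its single nearest
#' unflagged value); `"previous"` carries the last unflagged value
#' forward (leading flagged days take the first unflagged value).
#' Unflagged records are never altered, replacements land in
#' `corrected_cm` with the strategy recorded in `correction`, and the
#' operation is idempotent.
#'
#' @param series a [HeightSeries-class] with at least one unflagged record.
#' @param strategy `"linear"` (default) or `"previous"`.
#' @return a [HeightSeries-class].
#' @export
interpolateFlagged <- function(series, strategy = c("linear", "previous")) {
  strategy <- match.arg(strategy)
  rec <- records(series)
  ok <- which(!rec$flagged)
  if (length(ok) == 0L)
    stopCorrection("all %d records are flagged; nothing to interpolate from", nrow(rec))
  bad <- which(rec$flagged)
  t <- as.numeric(rec$date)
  for (i in bad) {
    prev <- ok[ok < i]
    nxt <- ok[ok > i]
    if (strategy == "previous") {
      j <- if (length(prev)) max(prev) else min(nxt)
      rec$corrected_cm[i] <- rec$estimated_cm[j]
    } else {
      if (length(prev) && length(nxt)) {
        a <- max(prev); b <- min(nxt)
        w <- (t[i] - t[a]) / (t[b] - t[a])
        rec$corrected_cm[i] <- (1 - w) * rec$estimated_cm[a] + w * rec$estimated_cm[b]
      } else {
        j <- if (length(prev)) max(prev) else min(nxt)
        rec$corrected_cm[i] <- rec$estimated_cm[j]
      }
    }
    rec$correction[i] <- strategy
  }
  rec$corrected_cm[ok] <- rec$estimated_cm[ok]
  rec$correction[ok] <- "none"
  initialize(series, records = rec)
}

#' Mean and sample standard deviation of relative errors
#'
#' @param errors non-empty numeric vector of percent errors.
#' @return named numeric vector `c(mean = , sd = )`; `sd` uses the n - 1
#'   denominator (NA for a single value).
#' @export
summarizeErrors <- function(errors) {
  if (!is.numeric(errors) || length(errors) == 0L || any(!is.finite(errors)))
    stopInput("'errors' must be a non-empty finite numeric vector")
  c(mean = mean(errors), sd = stats::sd(errors))
}

#' Welch two-sample t comparison of two error populations
#'
#' Unequal-variance two-sample t statistic with Welch--Satterthwaite
#' degrees of freedom and a two-tailed p value, used to compare the error
#' columns of two feature pipelines (e.g. red band vs excess green).
#'
#' @param errorsA,errorsB numeric vectors of percent errors, length >= 2.
#' @return list with elements `t`, `p`, `df`.
#' @export
compareFeaturesT <- function(errorsA, errorsB) {
  for (e in list(errorsA, errorsB))
    if (!is.numeric(e) || length(e) < 2L || any(!is.finite(e)))
      stopInput("both error lists must be finite numeric vectors of length >= 2")
  ht <- stats::t.test(errorsA, errorsB, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Read or write a height series as CSV
#'
#' Columns: `date, estimated_cm, reference_cm, condition, light_wm2,
#' rain_mmh, flagged, corrected_cm, correction`. Missing optional columns
#' are tolerated on read.
#'
#' @param series a [HeightSeries-class].
#' @param path CSV path.
#' @return `writeHeightSeries`: `path` invisibly; `readHeightSeries`: a
#'   [HeightSeries-class].
#' @export
writeHeightSeries <- function(series, path) {
  rec <- records(series)
  rec$date <- format(rec$date, "%Y-%m-%d")
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHeightSeries
#' @export
readHeightSeries <- function(path) {
  if (!file.exists(path)) stopInput("series file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(df) ||
      !any(c("estimated_cm", "reference_cm") %in% names(df)))
    stopInput("series CSV needs a 'date' and an 'estimated_cm' or 'reference_cm' column")
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  s <- heightSeries(
    date = as.Date(df$date),
    estimatedCm = get("estimated_cm", NA_real_),
    referenceCm = get("reference_cm", NA_real_),
    condition = get("condition", "normal"),
    lightWm2 = get("light_wm2", NA_real_),
    rainMmh = get("rain_mmh", NA_real_),
    flagged = if ("flagged" %in% names(df)) as.logical(df$flagged) else NULL)
  rec <- s@records
  if ("corrected_cm" %in% names(df)) rec$corrected_cm <- df$corrected_cm
  if ("correction" %in% names(df)) rec$correction <- df$correction
  initialize(s, records = rec)
}

#' Bundled field-deployment error tables
#'
#' Daily results of a 48-day field deployment (1 July -- 17 August) of the
#' marker-bar pipeline over a rice paddy, one table per feature: the
#' manual reference height, the automatic estimate and its relative
#' error, with the rice colour phase and field condition for each day.
#' These are the package's benchmark series for the evaluation
#' statistics.
#'
#' @param feature `"excess_green"` or `"red_band"`.
#' @return data.frame with columns `date`, `rice_color`, `condition`,
#'   `reference_cm`, `estimated_cm`, `relative_error_pct`.
#' @examples
#' summarizeErrors(fieldTrialErrors("excess_green")$relative_error_pct)
#' @export
fieldTrialErrors <- function(feature = c("excess_green", "red_band")) {
  feature <- match.arg(feature)
  path <- system.file("extdata",
                      sprintf("field_trial_%s.csv", feature),
                      package = "cropheight", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
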