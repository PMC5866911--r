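#' THI category labels and thresholds
#'
#' Days are classified by the maximum hourly temperature-humidity index
#' (THI) into four heat-load categories. The thresholds (in degrees
#' Celsius THI) are lower-inclusive: Normal < 23.33, 23.33 <= Alert <
#' 26.11, 26.11 <= Danger < 28.88, Emergency >= 28.88.
#'
#' @format `thi_categories()` returns the four ordered category labels;
#'   `thi_thresholds()` the three cut points in degrees Celsius.
#' @export
thi_categories <- function() c("Normal", "Alert", "Danger", "Emergency")

#' @rdname thi_categories
#' @export
thi_thresholds <- function() {
  c(Alert = 23.33, Danger = 26.11, Emergency = 28.88)
}

#' Temperature-humidity index
#'
#' Computes the hourly THI from ambient temperature and relative humidity:
#' \deqn{THI = T - (0.55 - 0.0055\,RH)(T - 14.5)}
#' with T in degrees Celsius and RH in percent (0-100). The formula is
#' evaluated exactly, with no clamping.
#'
#' @param temp_c numeric, ambient temperature in degrees Celsius.
#' @param rh_pct numeric, relative humidity in percent, within \[0, 100\].
#' @return THI in degrees Celsius, same length as the inputs.
#' @examples
#' compute_thi(30, 50)  # 25.7375
#' @export
compute_thi <- function(temp_c, rh_pct) {
  if (!is.numeric(temp_c) || !is.numeric(rh_pct))
    stop_invalid("temp_c and rh_pct must be numeric")
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0) || any(rh_pct > 100))
    stop_invalid("rh_pct must lie within [0, 100] percent")
  temp_c - (0.55 - 0.0055 * rh_pct) * (temp_c - 14.5)
}

#' Classify a daily maximum THI into a heat-load category
#'
#' Lower bounds are inclusive, upper bounds exclusive: a maximum THI of
#' exactly 23.33 is Alert and 28.88 is Emergency.
#'
#' @param max_thi_c numeric vector of daily maximum THI (degrees Celsius).
#' @param thresholds three strictly increasing cut points; defaults to
#'   [thi_thresholds()].
#' @return ordered factor with levels Normal < Alert < Danger < Emergency.
#' @export
thi_category <- function(max_thi_c, thresholds = thi_thresholds()) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop_invalid("thresholds must be three strictly increasing values")
  if (any(!is.finite(max_thi_c)))
    stop_invalid("max_thi_c must be finite")
  cut(max_thi_c, breaks = c(-Inf, thresholds, Inf),
      labels = thi_categories(), right = FALSE, ordered_result = TRUE)
}

#' Classify calendar days from an hourly weather series
#'
#' Computes hourly THI from the records, takes the per-day maximum and
#' assigns the heat-load category. Days with fewer than `min_hours`
#' hourly records are dropped (with a message) rather than imputed.
#'
#' @param weather data frame with columns `timestamp` (POSIXct or
#'   ISO-8601 character, UTC), `temp_c`, `rh_pct`.
#' @param min_hours minimum hourly records a day needs to be retained.
#' @param thresholds category cut points, see [thi_category()].
#' @return data frame with one row per retained day: `date`,
#'   `max_thi_c`, `category`.
#' @export
classify_days <- function(weather, min_hours = 18, thresholds = thi_thresholds()) {
  need <- c("timestamp", "temp_c", "rh_pct")
  if (!all(need %in% names(weather)))
    stop_invalid("weather must have columns: ", paste(need, collapse = ", "))
  if (nrow(weather) == 0L) {
    return(data.frame(date = as.Date(character()), max_thi_c = numeric(),
                      category = thi_category(numeric())))
  }
  ts <- weather$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC")
  date <- as.Date(ts, tz = "UTC")
  thi <- compute_thi(weather$temp_c, weather$rh_pct)
  n_hours <- tapply(thi, date, length)
  max_thi <- tapply(thi, date, max)
  keep <- n_hours >= min_hours
  if (any(!keep)) {
    message("classify_days: dropped ", sum(!keep), " day(s) with fewer than ",
            min_hours, " hourly records: ",
            paste(names(n_hours)[!keep], collapse = ", "))
  }
  out <- data.frame(
    date = as.Date(names(max_thi)[keep]),
    max_thi_c = unname(max_thi[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$date), , drop = FALSE]
  out$category <- thi_category(out$max_thi_c, thresholds)
  rownames(out) <- NULL
  out
}

#' Cubic regression of barn temperature on THI
#'
#' Ordinary least squares of barn temperature on powers 0..3 of the
#' outdoor THI, as used to check that outdoor THI predicts conditions
#' inside the barn.
#'
#' @param thi_c numeric vector of THI values (degrees Celsius).
#' @param barn_temp_c numeric vector of barn temperatures, same length.
#' @return an object of class `barn_thi_fit`: a list with `coefficients`
#'   (intercept and the three polynomial terms), `adj_r_squared`, and the
#'   underlying [stats::lm()] fit in `$fit`.
#' @export
fit_barn_model <- function(thi_c, barn_temp_c) {
  if (length(thi_c) != length(barn_temp_c))
    stop_invalid("thi_c and barn_temp_c must have the same length")
  ok <- is.finite(thi_c) & is.finite(barn_temp_c)
  thi_c <- thi_c[ok]; barn_temp_c <- barn_temp_c[ok]
  if (length(thi_c) < 5L)
    stop_invalid("fit_barn_model needs at least 5 complete pairs")
  if (length(unique(thi_c)) < 4L)
    stop_invalid("degenerate fit: THI values do not span a cubic design")
  fit <- stats::lm(barn_temp_c ~ thi_c + I(thi_c^2) + I(thi_c^3))
  co <- stats::coef(fit)
  names(co) <- c("intercept", "thi", "thi^2", "thi^3")
  structure(
    list(coefficients = co,
         adj_r_squared = summary(fit)$adj.r.squared,
         fit = fit),
    class = "barn_thi_fit"
  )
}

#' @export
print.barn_thi_fit <- function(x, ...) {
  cat("Cubic barn-temperature ~ THI regression\n")
  print(round(x$coefficients, 6))
  cat(sprintf("adjusted R-squared: %.3f\n", x$adj_r_squared))
  invisible(x)
}

#' Read an hourly weather table
#'
#' Expects a TSV/CSV with columns `timestamp` (ISO-8601), `temp_c`,
#' `rh_pct`; the delimiter is inferred from the file extension.
#'
#' @param path file path.
#' @return data frame with a parsed POSIXct `timestamp` (UTC).
#' @export
read_weather <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  w <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c", "rh_pct")
  if (!all(need %in% names(w)))
    stop_invalid("weather file must have columns: ", paste(need, collapse = ", "))
  w$timestamp <- as.POSIXct(w$timestamp, tz = "UTC")
  w
}

#' Write a day-classification table
#'
#' @param days output of [classify_days()].
#' @param path destination TSV.
#' @export
write_day_classes <- function(days, path) {
  out <- days
  out$category <- as.character(out$category)
  write_tsv(out, path)
}

#' Read a day-classification table written by [write_day_classes()]
#'
#' @param path TSV path.
#' @return data frame with `date` (Date), `max_thi_c`, `category`
#'   (ordered factor).
#' @export
read_day_classes <- function(path) {
  d <- read_tsv(path)
  d$date <- as.Date(d$date)
  d$category <- factor(d$category, levels = thi_categories(), ordered = TRUE)
  if (any(is.na(d$category)))
    stop_invalid("unknown THI category label in ", path)
  d
}
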