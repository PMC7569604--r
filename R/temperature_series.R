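#' Temperature series
#'
#' A time-stamped temperature record driving rate summation: ordered times in
#' hours from the start of the simulation and the temperature (deg C) holding
#' over the interval beginning at each time. Steps must be positive and at
#' most 24 h.
#'
#' @param time_h numeric vector of strictly increasing times, hours.
#' @param temp temperatures, deg C, same length.
#' @return object of class `temp_series` (a data.frame with columns `time_h`
#'   and `temp`).
#' @seealso [temp_series_constant()], [temp_series_sine()],
#'   [read_temperature_series()]
#' @export
temp_series <- function(time_h, temp) {
  stopifnot(is.numeric(time_h), is.numeric(temp), length(time_h) == length(temp),
            length(time_h) >= 2)
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(dt > 24)) stop("temperature records must be at most 24 h apart")
  if (any(!is.finite(temp))) stop("temperatures must be finite")
  structure(data.frame(time_h = time_h, temp = temp),
            class = c("temp_series", "data.frame"))
}

#' @export
print.temp_series <- function(x, ...) {
  cat(sprintf("Temperature series: %.1f days in %d records, %.1f-%.1f degC\n",
              max(x$time_h) / 24, nrow(x), min(x$temp), max(x$temp)))
  invisible(x)
}

#' Constant temperature series
#'
#' @param temp constant temperature, deg C.
#' @param days length of the series, days.
#' @param step record interval, hours (must divide 24).
#' @return a [temp_series()].
#' @export
temp_series_constant <- function(temp, days, step = 24) {
  check_step(step)
  tt <- seq(0, days * 24, by = step)
  temp_series(tt, rep(temp, length(tt)))
}

#' Sinusoidal daily temperature cycle
#'
#' Sine-wave day around a mean temperature: minimum `mean - amplitude` at
#' midnight, maximum `mean + amplitude` at noon. Sampled at `step`-hour
#' intervals the series spans exactly `[mean - amplitude, mean + amplitude]`
#' and its time average equals `mean` (full daily periods of an equally
#' sampled sine sum to zero).
#'
#' @param mean mean temperature, deg C.
#' @param amplitude half-range of the daily cycle, deg C (`>= 0`).
#' @param days length of the series, days.
#' @param step sampling interval, hours (must divide 24).
#' @return a [temp_series()].
#' @examples
#' s <- temp_series_sine(20, 5, days = 2, step = 1)
#' range(s$temp) # 15 25
#' @export
temp_series_sine <- function(mean, amplitude, days, step = 1) {
  check_step(step)
  if (amplitude < 0) stop("amplitude must be non-negative")
  tt <- seq(0, days * 24, by = step)
  temp_series(tt, mean - amplitude * cospi(tt / 12))
}

#' Read a temperature log from delimited text
#'
#' Expects two columns: a timestamp (ISO date-time, parsed with
#' [as.POSIXct()], or a plain numeric hour offset) and a temperature in
#' deg C. Times are converted to hours since the first record.
#'
#' @param path file path; comma-, tab- or whitespace-delimited with a header.
#' @return a [temp_series()].
#' @export
read_temperature_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) d <- utils::read.table(path, header = TRUE,
                                          stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("temperature log needs a timestamp and a temperature column")
  ts <- d[[1]]
  if (is.numeric(ts)) {
    hours <- ts - ts[1]
  } else {
    pt <- as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S",
                                                    "%Y-%m-%d %H:%M"))
    if (anyNA(pt)) stop("could not parse timestamps in ", path)
    hours <- as.numeric(difftime(pt, pt[1], units = "hours"))
  }
  temp_series(hours, as.numeric(d[[2]]))
}

check_step <- function(step) {
  if (!is.numeric(step) || step <= 0 || abs(24 / step - round(24 / step)) > 1e-9) {
    stop("step (hours) must be positive and divide 24")
  }
  invisible(TRUE)
}
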