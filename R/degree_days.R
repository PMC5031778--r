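#' Daily degree-days by the simple-average method with horizontal cutoff
#'
#' Converts a day's minimum and maximum temperature into thermal time above a
#' lower developmental threshold, capped at an upper threshold. Temperatures
#' are first clamped into `[lower, upper]` (the horizontal-cutoff rule), then
#' averaged, and the lower threshold subtracted, with a floor at zero:
#' \deqn{DD = \max\{0, (\mathrm{clamp}(t_{max}) + \mathrm{clamp}(t_{min}))/2 - l\}}
#'
#' Defaults are the codling-moth thresholds of 10 degC (lower) and 31 degC
#' (upper), so a single day can contribute at most `upper - lower` = 21
#' degree-days.
#'
#' @param tmin,tmax Daily minimum and maximum air temperature (degC). Vectors
#'   are recycled to a common length. Fahrenheit data must be converted
#'   before calling.
#' @param lower,upper Lower and upper developmental thresholds (degC);
#'   `lower < upper` is required.
#' @return Numeric vector of degree-days (degC-days), in `[0, upper - lower]`.
#' @examples
#' daily_degree_days(15, 25)            # 10
#' daily_degree_days(5, 9)              # 0: whole day below threshold
#' daily_degree_days(33, 35)            # 21: capped at the upper threshold
#' @export
daily_degree_days <- function(tmin, tmax, lower = 10, upper = 31) {
  check_thresholds(lower, upper)
  if (length(tmin) != length(tmax)) {
    n <- max(length(tmin), length(tmax))
    tmin <- rep_len(tmin, n)
    tmax <- rep_len(tmax, n)
  }
  bad <- which(tmin > tmax)
  if (length(bad) > 0) {
    abort(
      paste0("`tmin` exceeds `tmax` for ", length(bad), " record(s), e.g. (",
             tmin[bad[1]], ", ", tmax[bad[1]], ")."),
      class = "pcm_invalid_record"
    )
  }
  # clamp both temperatures into [lower, upper] before averaging
  tmax_c <- pmin(pmax(tmax, lower), upper)
  tmin_c <- pmin(pmax(tmin, lower), upper)
  pmax(0, (tmax_c + tmin_c) / 2 - lower)
}

#' Accumulate degree-days from an anchor (biofix) date
#'
#' Computes daily and cumulative degree-days from a daily temperature table,
#' anchored at `anchor` (typically the biofix, the first sustained moth
#' capture). The anchor day itself contributes zero to the running total:
#' `cumulative_dd` at the anchor is 0 and accumulation starts the day after,
#' so the anchor is the origin of the degree-day axis used by the flight
#' models.
#'
#' @param temps Data frame with columns `date` (`Date` or ISO-8601 character),
#'   `tmin_c`, `tmax_c` (degC); one row per day, dates unique.
#' @param anchor Anchor date (biofix). Must lie within the date range of
#'   `temps`.
#' @param lower,upper Developmental thresholds passed to
#'   [daily_degree_days()].
#' @param max_gap Largest run of missing days that will be filled by linear
#'   interpolation of `tmin_c`/`tmax_c` (a message reports the filled dates).
#'   The default `0` makes any gap an error.
#' @return A tibble with columns `date`, `daily_dd`, `cumulative_dd` covering
#'   `anchor` through the last temperature date. Attributes `anchor`, `lower`,
#'   `upper` record the configuration.
#' @examples
#' temps <- tibble::tibble(
#'   date = as.Date("2007-06-01") + 0:2, tmin_c = 15, tmax_c = 25
#' )
#' accumulate_degree_days(temps, anchor = "2007-06-01")
#' @export
accumulate_degree_days <- function(temps, anchor, lower = 10, upper = 31,
                                   max_gap = 0) {
  check_thresholds(lower, upper)
  temps <- as_temperature_table(temps)
  anchor <- as.Date(anchor)
  if (length(anchor) != 1 || is.na(anchor)) {
    abort("`anchor` must be a single valid date.")
  }
  if (anchor > max(temps$date)) {
    abort("`anchor` lies after the last temperature record; nothing to accumulate.",
          class = "pcm_empty_series")
  }
  if (anchor < min(temps$date)) {
    abort("`anchor` lies before the first temperature record.",
          class = "pcm_gap_error")
  }
  temps <- fill_temperature_gaps(temps, max_gap)
  out <- temps[temps$date >= anchor, , drop = FALSE]
  daily <- daily_degree_days(out$tmin_c, out$tmax_c, lower, upper)
  res <- tibble(
    date = out$date,
    daily_dd = daily,
    # anchor day contributes 0: accumulation runs over (anchor, d]
    cumulative_dd = cumsum(daily) - daily[1]
  )
  attr(res, "anchor") <- anchor
  attr(res, "lower") <- lower
  attr(res, "upper") <- upper
  res
}

check_thresholds <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1 ||
      length(upper) != 1 || !(lower < upper)) {
    abort("Thresholds must satisfy `lower < upper`.")
  }
  invisible(NULL)
}

as_temperature_table <- function(temps) {
  temps <- as_tibble(temps)
  need <- c("date", "tmin_c", "tmax_c")
  missing_cols <- setdiff(need, names(temps))
  if (length(missing_cols) > 0) {
    abort(paste0("`temps` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  temps$date <- as.Date(temps$date)
  if (anyNA(temps$date)) abort("`temps$date` contains unparseable dates.")
  if (anyDuplicated(temps$date)) {
    abort("`temps` has duplicated dates.", class = "pcm_invalid_record")
  }
  arrange(temps[need], .data$date)
}

fill_temperature_gaps <- function(temps, max_gap) {
  full <- seq(min(temps$date), max(temps$date), by = "day")
  missing_days <- as.Date(setdiff(full, temps$date), origin = "1970-01-01")
  if (length(missing_days) == 0) return(temps)
  runs <- split(missing_days, cumsum(c(TRUE, diff(missing_days) > 1)))
  too_long <- vapply(runs, length, integer(1)) > max_gap
  if (any(too_long)) {
    bad <- format(do.call(c, unname(runs[too_long])))
    abort(
      paste0("Temperature series has gap(s) longer than `max_gap` = ",
             max_gap, " day(s): ", paste(bad, collapse = ", "), "."),
      class = "pcm_gap_error"
    )
  }
  filled <- tibble(
    date = full,
    tmin_c = stats::approx(temps$date, temps$tmin_c, xout = full)$y,
    tmax_c = stats::approx(temps$date, temps$tmax_c, xout = full)$y
  )
  inform(paste0("Filled ", length(missing_days),
                " missing day(s) by linear interpolation: ",
                paste(format(missing_days), collapse = ", ")))
  filled
}
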