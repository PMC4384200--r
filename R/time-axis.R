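#' Two-week time axis anchored on a fixed weekday
#'
#' Builds the grid of two-week averaging periods used throughout the package.
#' Period starts fall on a fixed weekday (Wednesday by convention for passive
#' two-week samplers) and are spaced exactly 14 days apart; each period covers
#' the half-open interval `[start, start + 14)` days.
#'
#' @param start_date,end_date `Date` (or coercible) span to cover. The first
#'   period start is the first `anchor_weekday` on or after `start_date`; the
#'   last period start is the latest grid date whose full 14-day period ends on
#'   or before `end_date` (i.e. start `<= end_date - 14`).
#' @param anchor_weekday Weekday name anchoring period starts
#'   (default `"Wednesday"`).
#' @return An object of class `st_time_axis`: a `Date` vector of period starts
#'   with attribute `period_days = 14`.
#' @examples
#' ax <- build_time_axis(as.Date("1999-01-06"), as.Date("1999-03-03"))
#' length(ax)  # 4 periods
#' @export
build_time_axis <- function(start_date, end_date, anchor_weekday = "Wednesday") {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(!is.na(start_date), !is.na(end_date))
  if (start_date >= end_date) {
    stop("start_date must precede end_date")
  }
  wd <- match.arg(anchor_weekday, c(
    "Monday", "Tuesday", "Wednesday", "Thursday",
    "Friday", "Saturday", "Sunday"
  ))
  target <- match(wd, c(
    "Monday", "Tuesday", "Wednesday", "Thursday",
    "Friday", "Saturday", "Sunday"
  ))
  # weekday of start_date, Monday = 1
  dow <- as.integer(format(start_date, "%u"))
  first <- start_date + ((target - dow) %% 7L)
  last_allowed <- end_date - 14L
  if (first > last_allowed) {
    stop("span shorter than one 14-day period after anchoring")
  }
  starts <- seq(first, last_allowed, by = 14L)
  structure(starts, class = c("st_time_axis", "Date"), period_days = 14L)
}

#' @export
print.st_time_axis <- function(x, ...) {
  cat(
    "<st_time_axis> ", length(x), " two-week periods: ",
    format(x[1]), " .. ", format(x[length(x)] + 13L), "\n",
    sep = ""
  )
  invisible(x)
}

#' Map timestamps to two-week period indices
#'
#' Each timestamp maps to the period whose half-open interval
#' `[start, start + 14)` contains it; timestamps outside the axis map to `NA`.
#'
#' @param dates `Date` vector (or coercible).
#' @param axis An [build_time_axis()] object.
#' @return Integer vector of period indices (1-based), `NA` where off-axis.
#' @export
assign_period <- function(dates, axis) {
  stopifnot(inherits(axis, "st_time_axis"), length(axis) > 0)
  dates <- as.Date(dates)
  idx <- findInterval(as.numeric(dates), as.numeric(axis))
  idx[idx < 1L] <- NA_integer_
  off_end <- !is.na(idx) & (as.numeric(dates) >= as.numeric(axis[pmin(idx, length(axis))]) + 14)
  idx[off_end] <- NA_integer_
  as.integer(idx)
}

#' Realign an off-grid two-week sample onto the axis
#'
#' Two-week samples centred one week off the main grid are treated as if made
#' one week earlier or later, mapping them onto the grid period exactly seven
#' days away. On-grid sample starts map to their own period. Any other offset
#' is an error: only one-week shifts are a sanctioned realignment.
#'
#' @param sample_start `Date` vector of sample start dates.
#' @param axis An [build_time_axis()] object.
#' @return Integer vector of period indices.
#' @export
realign_offgrid_sample <- function(sample_start, axis) {
  stopifnot(inherits(axis, "st_time_axis"))
  sample_start <- as.Date(sample_start)
  offset <- (as.numeric(sample_start) - as.numeric(axis[1])) %% 14
  out <- rep(NA_integer_, length(sample_start))
  ok0 <- offset == 0
  out[ok0] <- assign_period(sample_start[ok0], axis)
  ok7 <- offset == 7
  # one week off: snap to the grid start 7 days earlier (i.e. the period
  # containing the sample start), treating the sample as made 1 week earlier
  out[ok7] <- assign_period(sample_start[ok7] - 7L, axis)
  if (any(!ok0 & !ok7)) {
    bad <- sample_start[!ok0 & !ok7]
    stop(
      "sample start(s) ", paste(format(bad), collapse = ", "),
      " are off-grid by an offset other than 0 or 7 days; ",
      "only 1-week realignment is supported"
    )
  }
  if (anyNA(out)) {
    stop("realigned sample start falls outside the time axis")
  }
  out
}
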