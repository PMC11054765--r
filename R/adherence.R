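#' Device-wear intervals from a 15-min temperature log
#'
#' Stand-in wear-time rule for an in-device temperature sensor, built on
#' threshold hysteresis with slope assists: wear starts at the first sample
#' with `temp >= on_threshold`, or with `temp >= off_threshold` and a rise
#' of at least `min_slope` since the previous sample (donning is seen first
#' as a steep rise through the hysteresis band); wear ends at the first
#' sample with `temp < off_threshold`, or with a fall of at least
#' `fall_slope` (doffing is seen first as a steep fall from skin
#' temperature). Interval boundaries snap to sample timestamps. A gap of
#' more than `max_gap_h` hours in the log closes any spanning interval and
#' raises a gap warning.
#'
#' @param log Temperature tibble `(time, temp_c)` at nominal 15-min spacing.
#' @param on_threshold,off_threshold Hysteresis thresholds in deg C
#'   (`on_threshold > off_threshold`).
#' @param min_slope Rise (deg C per sample) that starts wear inside the
#'   hysteresis band.
#' @param fall_slope Fall (deg C per sample) that ends wear.
#' @param max_gap_h Log gap (hours) that splits intervals.
#' @return Interval tibble `(on, off)` with attribute `algorithm`.
#' @export
wear_intervals_from_temperature <- function(log, on_threshold = 27,
                                            off_threshold = 25,
                                            min_slope = 0.5, fall_slope = 2,
                                            max_gap_h = 2) {
  if (nrow(log) == 0) abort("empty temperature log", class = "cptstress_error_input")
  if (on_threshold <= off_threshold) {
    abort("`on_threshold` must exceed `off_threshold` (hysteresis)",
          class = "cptstress_error_config")
  }
  tt <- as.numeric(log$time)
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("temperature timestamps must be strictly increasing",
          class = "cptstress_error_format")
  }
  temp <- log$temp_c
  dtemp <- c(0, diff(temp))
  gap_before <- c(FALSE, diff(tt) > max_gap_h * 3600)
  if (any(gap_before)) {
    warn(sprintf("temperature log has %d gap(s) > %g h; spanning wear intervals split",
                 sum(gap_before), max_gap_h),
         class = "cptstress_warning_gap")
  }
  worn <- FALSE
  on_t <- c(); off_t <- c(); cur_on <- NA_real_
  for (i in seq_along(temp)) {
    if (worn && gap_before[i]) {
      on_t <- c(on_t, cur_on); off_t <- c(off_t, tt[i - 1])
      worn <- FALSE
    }
    if (!worn) {
      if (temp[i] >= on_threshold ||
          (temp[i] >= off_threshold && dtemp[i] >= min_slope && !gap_before[i])) {
        worn <- TRUE; cur_on <- tt[i]
      }
    } else {
      if (temp[i] < off_threshold || (-dtemp[i] >= fall_slope && !gap_before[i])) {
        on_t <- c(on_t, cur_on); off_t <- c(off_t, tt[i])
        worn <- FALSE
      }
    }
  }
  if (worn) { on_t <- c(on_t, cur_on); off_t <- c(off_t, tt[length(tt)] + 900) }
  out <- if (length(on_t)) {
    tibble(on = as.POSIXct(on_t, origin = "1970-01-01", tz = "UTC"),
           off = as.POSIXct(off_t, origin = "1970-01-01", tz = "UTC"))
  } else new_interval_set()
  attr(out, "algorithm") <- list(
    name = "hysteresis_slope_standin", on_threshold = on_threshold,
    off_threshold = off_threshold, min_slope = min_slope, fall_slope = fall_slope
  )
  out
}

#' Classify strides by device-wear condition
#'
#' A stride is counted as in-device iff its timestamp falls in a half-open
#' wear interval `[on, off)`; all others are non-device. Strides outside
#' the temperature log's coverage are counted non-device with a coverage
#' warning.
#'
#' @param strides Stride tibble with POSIXct `time`.
#' @param wear Device-wear interval tibble `(on, off)`.
#' @param coverage Optional length-2 POSIXct span of the temperature log;
#'   strides outside it trigger a coverage warning.
#' @return Tibble `(date, strides_in_device, strides_non_device)`, one row
#'   per calendar day with any strides.
#' @export
classify_strides <- function(strides, wear, coverage = NULL) {
  if (nrow(strides) == 0) {
    return(tibble(date = as.Date(character()), strides_in_device = integer(),
                  strides_non_device = integer()))
  }
  if (!is.null(coverage)) {
    outside <- strides$time < coverage[1] | strides$time >= coverage[2]
    if (any(outside)) {
      warn(sprintf("%d stride(s) outside temperature-log coverage counted non-device",
                   sum(outside)),
           class = "cptstress_warning_coverage")
    }
  }
  in_dev <- in_intervals(strides$time, wear)
  tibble(date = utc_day(strides$time), in_dev = in_dev) |>
    dplyr::summarise(
      strides_in_device = sum(.data$in_dev),
      strides_non_device = sum(!.data$in_dev),
      .by = "date"
    ) |>
    dplyr::arrange(.data$date)
}

#' Adherence to using the offloading device
#'
#' Adherence is the percentage of strides taken while wearing the
#' offloading device, of the total strides taken over valid monitoring
#' days.
#'
#' @param counts Per-day condition counts from [classify_strides()].
#' @param valid_dates Dates (class `Date`) of valid monitoring days;
#'   `NULL` uses all days in `counts`.
#' @return One-row tibble `(adherence_percent, strides_in_device,
#'   strides_total, n_days)`.
#' @export
adherence_percent <- function(counts, valid_dates = NULL) {
  use <- if (is.null(valid_dates)) counts else counts[counts$date %in% valid_dates, ]
  total <- sum(use$strides_in_device) + sum(use$strides_non_device)
  if (nrow(use) == 0 || total == 0) {
    abort("adherence undefined: no strides on valid days",
          class = "cptstress_error_undefined_adherence")
  }
  tibble(
    adherence_percent = 100 * sum(use$strides_in_device) / total,
    strides_in_device = sum(use$strides_in_device),
    strides_total = total,
    n_days = nrow(use)
  )
}
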