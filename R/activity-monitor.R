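accel_rate <- function(accel) {
  attr(accel, "sampling_rate") %||% {
    dt <- diff(as.numeric(accel$time[1:2]))
    1 / dt
  }
}

#' Detect activity-monitor wear from acceleration
#'
#' The monitor is considered worn while the acceleration signal moves:
#' windows in which the standard deviation of the vector magnitude reaches
#' `std_threshold` are wear; adjacent wear windows are merged. This is a
#' stand-in wear rule validated on synthetic ground truth.
#'
#' @param accel Acceleration tibble `(time, ax_g, ay_g, az_g)`.
#' @param window Window length in seconds.
#' @param std_threshold SD threshold in g; a threshold of 0 marks the whole
#'   record as wear.
#' @return Interval tibble `(on, off)`.
#' @export
detect_monitor_wear <- function(accel, window = 60, std_threshold = 0.01) {
  if (nrow(accel) == 0) abort("empty acceleration series", class = "cptstress_error_input")
  stopifnot(window > 0)
  fs <- accel_rate(accel)
  vm <- sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2)
  per <- max(1L, round(window * fs))
  nwin <- ceiling(length(vm) / per)
  grp <- rep(seq_len(nwin), each = per, length.out = length(vm))
  sds <- tapply(vm, grp, sd)
  sds[is.na(sds)] <- 0
  worn <- as.vector(sds) >= std_threshold
  if (!any(worn)) return(new_interval_set())
  r <- rle(worn)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  t0 <- accel$time[1]
  iv <- tibble(
    on = t0 + (starts[r$values] - 1) * window,
    off = t0 + pmin(ends[r$values] * window,
                    as.numeric(accel$time[nrow(accel)] - t0, units = "secs") + 1 / fs)
  )
  merge_intervals(iv)
}

#' Detect strides from trunk acceleration
#'
#' Stand-in for a proprietary stride-count algorithm, validated only
#' against synthetic ground truth: the vertical channel is band-pass
#' filtered to the gait band (0.5--3 Hz, 2nd-order Butterworth applied
#' forward-backward), and peaks at least `min_distance_s` apart whose
#' filtered amplitude reaches `prominence_g` are counted as strides.
#'
#' @param accel Acceleration tibble `(time, ax_g, ay_g, az_g)`; sampling
#'   rate must be at least 20 Hz.
#' @param band Pass band in Hz.
#' @param min_distance_s Minimum inter-stride interval in s.
#' @param prominence_g Minimum filtered peak height in g.
#' @return Stride tibble `(time)` with attribute `source = "detected"`.
#' @export
detect_strides <- function(accel, band = c(0.5, 3), min_distance_s = 0.4,
                           prominence_g = 0.3) {
  fs <- accel_rate(accel)
  if (fs < 20) abort("sampling rate must be >= 20 Hz", class = "cptstress_error_input")
  x <- accel$az_g - median(accel$az_g)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  pk <- pracma::findpeaks(xf, minpeakheight = prominence_g,
                          minpeakdistance = max(1L, round(min_distance_s * fs)))
  times <- if (is.null(pk)) accel$time[0] else sort(accel$time[pk[, 2]])
  out <- tibble(time = times)
  attr(out, "source") <- "detected"
  out
}

#' Daily stride counts and valid monitoring days
#'
#' Groups strides by calendar day, computes activity-monitor wear hours per
#' day, flags days with at least `min_wear_h` hours of monitor wear as
#' valid, and averages stride counts over valid days only. Fewer than
#' `min_valid_days` valid days is a protocol failure ("non-adherent
#' participant").
#'
#' @param strides Stride tibble with POSIXct `time`.
#' @param wear Monitor-wear interval tibble `(on, off)`.
#' @param min_wear_h Hours of wear required for a valid day (default 12).
#' @param min_valid_days Valid days required (default 4).
#' @return Tibble `(date, stride_count, monitor_wear_hours, valid)` with
#'   attribute `mean_strides_per_day` (mean over valid days).
#' @export
daily_activity <- function(strides, wear, min_wear_h = 12, min_valid_days = 4L) {
  if (nrow(wear) == 0) {
    abort("no monitor wear intervals", class = "cptstress_error_input")
  }
  d_lo <- min(utc_day(wear$on), if (nrow(strides)) utc_day(min(strides$time)))
  d_hi <- max(utc_day(wear$off), if (nrow(strides)) utc_day(max(strides$time)))
  dates <- seq(d_lo, d_hi, by = "day")
  per_day <- purrr::map_dfr(dates, function(d) {
    d0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    wear_d <- clip_intervals(wear, d0, d0 + 86400)
    n <- if (nrow(strides) == 0) 0L else sum(utc_day(strides$time) == d)
    tibble(date = d, stride_count = n, monitor_wear_hours = interval_hours(wear_d))
  })
  per_day$valid <- per_day$monitor_wear_hours >= min_wear_h
  n_valid <- sum(per_day$valid)
  if (n_valid < min_valid_days) {
    abort(
      sprintf("non-adherent participant: %d valid days (>= %g h wear), minimum %d",
              n_valid, min_wear_h, min_valid_days),
      class = "cptstress_error_non_adherent",
      n_valid_days = n_valid
    )
  }
  attr(per_day, "mean_strides_per_day") <- mean(per_day$stride_count[per_day$valid])
  per_day
}
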