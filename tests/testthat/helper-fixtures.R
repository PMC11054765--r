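# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files a test itself writes.

# Minimal two-sensor geometry for hand-built pressure series.
tiny_geometry <- function(n_sensors = 2, area_cm2 = 2) {
  tibble::tibble(
    sensor = sprintf("s%03d", seq_len(n_sensors)),
    x_mm = (seq_len(n_sensors) - 1) * 10, y_mm = 0,
    area_cm2 = area_cm2
  )
}

# Pressure series of rectangular contacts: each contact holds `p_kpa[i]` on
# all sensors for exactly `contact_s` of integrated time (trapezoid of a
# rectangle), separated by `gap_s` of zeros.
rect_series <- function(p_kpa, fs = 100, contact_s = 1, gap_s = 0.5,
                        n_sensors = 2, area_cm2 = 2) {
  geom <- tiny_geometry(n_sensors, area_cm2)
  n_on <- round(contact_s * fs) + 1   # n+1 frames -> trapz = P * contact_s
  n_off <- round(gap_s * fs)
  col <- unlist(lapply(p_kpa, function(p) c(rep(0, n_off), rep(p, n_on))))
  col <- c(col, rep(0, n_off))
  frames <- tibble::as_tibble(
    matrix(rep(col, n_sensors), ncol = n_sensors,
           dimnames = list(NULL, geom$sensor))
  )
  frames <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_along(col) - 1) / fs), frames
  )
  pressure_frames(frames, dialect = "insole", sampling_rate = fs,
                  geometry = geom)
}

tiny_mask <- function(series, sensors = NULL) {
  geom <- attr(series, "geometry")
  region_mask(geom, sensors = sensors %||% geom$sensor)
}

# Profile with every generative range pinned to a point, so stream-level
# expectations are deterministic functions of the arguments.
fixed_profile <- function(adherence = 0.5, strides = 2000,
                          pti_in = 66.2, ppp_in = 140.6,
                          pti_non = 72.2, ppp_non = 178.7,
                          tsr_in = 0.66, tsr_non = 1.45,
                          wear_on = 8, wear_off = 20,
                          monitoring_days = 6, style = "AU", seed = 1) {
  cfg <- synth_config(
    style = style,
    adherence_range = c(adherence, adherence),
    daily_strides_range = c(strides, strides),
    pti_in_range = c(pti_in, pti_in), ppp_in_range = c(ppp_in, ppp_in),
    pti_non_range = c(pti_non, pti_non), ppp_non_range = c(ppp_non, ppp_non),
    tsr_in_range = c(tsr_in, tsr_in), tsr_non_range = c(tsr_non, tsr_non),
    wear_on_range = c(wear_on, wear_on), wear_off_range = c(wear_off, wear_off),
    monitoring_days = monitoring_days,
    healed_fraction = 0
  )
  generate_profile(seed, cfg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_day_strides <- function(dates, counts, start_h = 9, cadence = 1.1) {
  times <- unlist(mapply(function(d, n) {
    as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC")) +
      start_h * 3600 + (seq_len(n) - 1) * cadence
  }, dates, counts, SIMPLIFY = FALSE))
  tibble::tibble(time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"))
}

day_intervals <- function(dates, on_h, off_h) {
  midnight <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  tibble::tibble(on = midnight + on_h * 3600, off = midnight + off_h * 3600)
}

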