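const_log <- function(temp, hours = 48, start = "2023-05-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(time = t0 + seq(0, hours * 3600 - 900, by = 900),
                 temp_c = temp)
}

test_that("wear intervals follow the temperature hysteresis", {
  expect_equal(nrow(wear_intervals_from_temperature(const_log(21))), 0)

  full <- wear_intervals_from_temperature(const_log(32))
  expect_equal(nrow(full), 1)
  expect_equal(cptstress:::interval_hours(full), 48, tolerance = 0.3)

  expect_error(
    wear_intervals_from_temperature(const_log(30), on_threshold = 25,
                                    off_threshold = 27),
    class = "cptstress_error_config"
  )
})

test_that("wear on/off recover a daily schedule within two samples", {
  p <- fixed_profile(wear_on = 8, wear_off = 20, monitoring_days = 6)
  log <- simulate_temperature_log(p, noise_sd = 0)
  wear <- wear_intervals_from_temperature(log)
  truth <- cptstress:::profile_wear_schedule(p)
  expect_equal(nrow(wear), nrow(truth))
  on_err <- abs(as.numeric(wear$on) - as.numeric(truth$on))
  off_err <- abs(as.numeric(wear$off) - as.numeric(truth$off))
  expect_lte(max(on_err), 1800)    # within 2 samples of 15 min
  expect_lte(max(off_err), 1800)
})

test_that("log gaps longer than 2 h split spanning intervals", {
  log <- const_log(32, hours = 24)
  gap <- log$time > log$time[1] + 6 * 3600 & log$time <= log$time[1] + 9.5 * 3600
  log_gap <- log[!gap, ]
  expect_warning(
    w <- wear_intervals_from_temperature(log_gap),
    class = "cptstress_warning_gap"
  )
  expect_equal(nrow(w), 2)
})

test_that("stride classification is a half-open partition", {
  p <- fixed_profile(adherence = 0.481, strides = 3000, monitoring_days = 6)
  s <- simulate_stride_stream(p, seed = 8)
  truth <- cptstress:::profile_wear_schedule(p)

  counts <- classify_strides(s, truth)
  expect_equal(counts$strides_in_device + counts$strides_non_device,
               as.vector(table(s$day)))
  est <- adherence_percent(counts)
  expect_lt(abs(est$adherence_percent - 48.1), 2)

  # all-in / all-out degenerate cases
  s_in <- simulate_stride_stream(fixed_profile(adherence = 1), seed = 8)
  c_in <- classify_strides(s_in, truth)
  expect_equal(sum(c_in$strides_non_device), 0)
  expect_equal(adherence_percent(c_in)$adherence_percent, 100)
  s_out <- simulate_stride_stream(fixed_profile(adherence = 0), seed = 8)
  expect_equal(sum(classify_strides(s_out, truth)$strides_in_device), 0)

  # a stride exactly at `off` falls outside the half-open interval
  iv <- tibble::tibble(on = as.POSIXct("2023-05-01 08:00:00", tz = "UTC"),
                       off = as.POSIXct("2023-05-01 20:00:00", tz = "UTC"))
  at_bounds <- tibble::tibble(time = c(iv$on, iv$off))
  cb <- classify_strides(at_bounds, iv)
  expect_equal(cb$strides_in_device, 1)   # `on` in, `off` out
  expect_equal(cb$strides_non_device, 1)

  # shifting every clock by a constant leaves counts unchanged
  shift <- 3601
  c_shift <- classify_strides(dplyr::mutate(s, time = time + shift),
                              dplyr::mutate(truth, on = on + shift,
                                            off = off + shift))
  expect_equal(c_shift$strides_in_device, counts$strides_in_device)

  # enlarging a wear interval never decreases adherence
  bigger <- dplyr::mutate(truth, off = off + 3600)
  est_big <- adherence_percent(classify_strides(s, bigger))
  expect_gte(est_big$adherence_percent, est$adherence_percent)
})

test_that("adherence is the in-device share of valid-day strides", {
  counts <- tibble::tibble(
    date = as.Date("2023-05-01") + 0:1,
    strides_in_device = c(5000, 509),
    strides_non_device = c(5000, 491)
  )
  expect_equal(adherence_percent(counts[1, ])$adherence_percent, 50)
  expect_equal(adherence_percent(counts[2, ])$adherence_percent, 50.9)
  expect_equal(
    adherence_percent(counts, valid_dates = counts$date[2])$adherence_percent,
    50.9
  )
  empty <- dplyr::mutate(counts, strides_in_device = 0L, strides_non_device = 0L)
  expect_error(adherence_percent(empty),
               class = "cptstress_error_undefined_adherence")
})

test_that("strides outside log coverage warn and count as non-device", {
  iv <- tibble::tibble(on = as.POSIXct("2023-05-01 08:00:00", tz = "UTC"),
                       off = as.POSIXct("2023-05-01 20:00:00", tz = "UTC"))
  s <- tibble::tibble(time = as.POSIXct(c("2023-05-01 10:00:00",
                                          "2023-05-03 10:00:00"), tz = "UTC"))
  expect_warning(
    cc <- classify_strides(s, iv, coverage = c(iv$on - 7200, iv$off + 7200)),
    class = "cptstress_warning_coverage"
  )
  expect_equal(sum(cc$strides_in_device), 1)
  expect_equal(sum(cc$strides_non_device), 1)
})
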