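test_that("profile generation is deterministic and respects configured ranges", {
  p1 <- generate_profile(1)
  p2 <- generate_profile(1)
  expect_identical(p1, p2)
  expect_gte(p1$true_adherence, 0)
  expect_lte(p1$true_adherence, 1)
  cfg <- synth_config()
  expect_gte(p1$pti_in_device, cfg$pti_in_range[1])
  expect_lte(p1$pti_in_device, cfg$pti_in_range[2])
  expect_gte(p1$monitoring_days, 6)

  # degenerate range pins the drawn value exactly
  pinned <- generate_profile(5, synth_config(adherence_range = c(0.509, 0.509)))
  expect_equal(pinned$true_adherence, 0.509)

  expect_error(synth_config(adherence_range = c(0.7, 0.2)),
               class = "cptstress_error_config")
  expect_error(synth_config(monitoring_days = 5),
               class = "cptstress_error_config")
})

test_that("temperature log relaxes to the correct set-points", {
  # always worn: asymptote at the skin set-point
  p_on <- fixed_profile(wear_on = 0, wear_off = 24)
  log_on <- simulate_temperature_log(p_on, noise_sd = 0)
  expect_equal(tail(log_on$temp_c, 1), 32, tolerance = 1e-3)
  # essentially never worn, initialised at ambient: stays at ambient
  log_off <- simulate_temperature_log(fixed_profile(wear_on = 2, wear_off = 2.001),
                                      noise_sd = 0, init_temp_c = 21)
  expect_lt(max(abs(log_off$temp_c - 21)), 0.05)
  expect_error(simulate_temperature_log(p_on, noise_sd = -1),
               class = "cptstress_error_config")
})

test_that("a daily wear block produces a monotone rise then decay", {
  p <- fixed_profile(wear_on = 8, wear_off = 20, monitoring_days = 6)
  log <- simulate_temperature_log(p, noise_sd = 0)
  d1 <- log[as.Date(format(log$time, tz = "UTC")) == p$start_date, ]
  h <- as.numeric(d1$time - d1$time[1], units = "hours")
  rise <- d1$temp_c[h > 8 & h <= 20]
  decay <- d1$temp_c[h > 20]
  expect_true(all(diff(rise) > 0))
  expect_true(all(diff(decay) < 0))
  expect_equal(nrow(log), 6 * 96)   # exactly every 15 min
})

test_that("stride placement honours adherence ground truth and waking hours", {
  p1 <- fixed_profile(adherence = 1)
  s1 <- simulate_stride_stream(p1, seed = 3)
  expect_true(all(s1$in_wear_truth))
  wear <- cptstress:::profile_wear_schedule(p1)
  expect_true(all(cptstress:::in_intervals(s1$time, wear)))

  p0 <- fixed_profile(adherence = 0)
  s0 <- simulate_stride_stream(p0, seed = 3)
  expect_false(any(cptstress:::in_intervals(s0$time, wear)))

  hours <- as.numeric(format(s1$time, "%H"))
  expect_true(all(hours >= 6))       # no strides at night

  # inter-stride spacing within the physiological floor
  expect_true(all(diff(as.numeric(s1$time)) >= 0.4))
})

test_that("daily stride counts are drawn around the configured mean", {
  p <- fixed_profile(strides = 2146, monitoring_days = 6)
  s <- simulate_stride_stream(p, seed = 11)
  daily <- as.vector(table(s$day))
  expect_equal(length(daily), 6)
  expect_lt(abs(mean(daily) - 2146) / 2146, 0.05)
})

test_that("acceleration places one clipped peak per stride", {
  p <- fixed_profile(adherence = 1, strides = 2000)
  s <- simulate_stride_stream(p, seed = 7)[1:100, ]
  acc <- simulate_acceleration(s, sampling_rate = 100, seed = 2)
  expect_true(all(abs(acc$az_g) <= 6))
  det <- detect_strides(acc)
  expect_equal(nrow(det), 100)

  # no strides: detector finds nothing
  empty <- s[0, ]
  t0 <- s$time[1]
  acc0 <- simulate_acceleration(empty, 100, seed = 2, start = t0, end = t0 + 60)
  expect_equal(nrow(detect_strides(acc0)), 0)

  # a 10 g request saturates at the 6 g sensor range
  acc10 <- simulate_acceleration(s, 100, seed = 2, stride_amp_g = 10)
  expect_equal(max(acc10$az_g), 6)
})

test_that("pressure trials encode the analytic step PTI and exact PPP", {
  p <- fixed_profile()
  # explicit P = 200 kPa, T = 0.6 s: analytic PTI = 2 P T / pi
  tr <- simulate_pressure_trial(p, "in_device", n_steps = 4,
                                ppp = 200, pti = 2 * 200 * 0.6 / pi)
  g <- attr(tr, "generation")
  expect_equal(g$stance_s, 0.6)
  expect_equal(g$pti, 2 * 200 * 0.6 / pi, tolerance = 1e-12)

  # target PPP appears exactly as the max sensor value
  tr2 <- simulate_pressure_trial(p, "in_device", ppp = 119.4, pti = 66.2)
  sens <- attr(tr2, "geometry")$sensor
  expect_equal(max(as.matrix(tr2[sens])), 119.4)

  # requested number of disjoint stances
  tr16 <- simulate_pressure_trial(p, "in_device", n_steps = 16)
  expect_equal(nrow(detect_stance_phases(tr16)), 16)

  expect_error(simulate_pressure_trial(p, "in_device", pti = -1),
               class = "cptstress_error_config")
})

test_that("thermal pairs reproduce the target stress response exactly", {
  for (target in c(0.66, 1, 0, -0.4, 2)) {
    p <- fixed_profile(tsr_in = target)
    pair <- simulate_thermal_pair(p, "in_device")
    expect_equal(thermal_stress_response(pair)$tsr, target, tolerance = 1e-12)
  }
  # symmetry: target 1 means equal relative change on both feet
  p1 <- fixed_profile(tsr_in = 1)
  pr <- simulate_thermal_pair(p1, "in_device")
  expect_equal(pr$index_post / pr$index_pre, pr$contra_post / pr$contra_pre)
  # target 0 keeps the index foot unchanged
  p0 <- fixed_profile(tsr_in = 0)
  pr0 <- simulate_thermal_pair(p0, "in_device")
  expect_equal(pr0$index_post, pr0$index_pre)
  expect_error(simulate_thermal_pair(p1, "in_device", contra_rel_change = 0),
               class = "cptstress_error_infeasible")
})

test_that("cohort generation writes all streams and is reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(3, seed = 9, dir = d1, n_nl = 1)
  m2 <- generate_cohort(3, seed = 9, dir = d2, n_nl = 1)
  expect_equal(m1$truth, m2$truth)
  expect_identical(readLines(file.path(d1, "P01", "strides.csv")),
                   readLines(file.path(d2, "P01", "strides.csv")))
  expect_identical(m1$config_digest, m2$config_digest)

  # AU participants have thermal files, NL participants do not
  expect_true(file.exists(file.path(d1, "P01", "thermal.json")))
  expect_false(file.exists(file.path(d1, "P03", "thermal.json")))
  # NL non-device pressure is four platform trials
  expect_length(m1$files$P03$pressure_non, 4)
  expect_true(all(c("strides.csv", "monitor_wear.csv", "temperature.csv",
                    "pressure_in_device.csv") %in%
                    list.files(file.path(d1, "P02"))))
})
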