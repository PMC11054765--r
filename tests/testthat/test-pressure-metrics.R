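test_that("stance detection finds contiguous above-threshold runs", {
  zero <- rect_series(numeric(0), gap_s = 1)
  expect_equal(nrow(detect_stance_phases(zero)), 0)

  s16 <- rect_series(rep(100, 16))
  expect_equal(nrow(detect_stance_phases(s16)), 16)

  p <- fixed_profile()
  tr <- simulate_pressure_trial(p, "in_device", n_steps = 1,
                                ppp = 200, pti = 2 * 200 * 0.6 / pi)
  ph <- detect_stance_phases(tr)
  expect_equal(nrow(ph), 1)
  expect_lte(abs(ph$duration_s - 0.6), 1 / attr(tr, "sampling_rate") + 1e-9)

  expect_error(detect_stance_phases(rect_series(100)[0, ]),
               class = "cptstress_error_input")
})

test_that("midgait selection trims ends and enforces the 12-step minimum", {
  phases <- detect_stance_phases(rect_series(rep(100, 16)))
  kept <- select_midgait_steps(phases, trim = 2)
  expect_equal(nrow(kept), 12)
  expect_equal(kept$start, phases$start[3:14])

  ph15 <- detect_stance_phases(rect_series(rep(100, 15)))
  err <- expect_error(select_midgait_steps(ph15, trim = 2, min_steps = 12),
                      class = "cptstress_error_invalid_trial")
  expect_equal(err$n_midgait, 11)

  ph12 <- detect_stance_phases(rect_series(rep(100, 12)))
  expect_equal(select_midgait_steps(ph12, trim = 0), ph12)
})

test_that("step metrics reduce over the mask only", {
  # constant 100 kPa for exactly 1 s: ppp = pti = 100
  s <- rect_series(100, contact_s = 1)
  ph <- detect_stance_phases(s)
  m <- step_metrics(s, ph[1, ], tiny_mask(s))
  expect_equal(m$ppp, 100)
  expect_equal(m$pti, 100)

  # a hotter non-mask sensor never leaks into the regional curve
  s2 <- rect_series(100)
  s2$s002 <- s2$s002 * 3
  ph2 <- detect_stance_phases(s2)
  m2 <- step_metrics(s2, ph2[1, ], tiny_mask(s2, "s001"))
  expect_equal(m2$ppp, 100)

  bad_mask <- structure(list(label = "x", sensors = "nope"), class = "region_mask")
  expect_error(step_metrics(s, ph[1, ], bad_mask), class = "cptstress_error_input")
})

test_that("half-sine stances recover the analytic PTI 2PT/pi", {
  p <- fixed_profile()
  oracle <- function(P, T) 2 * P * T / pi
  for (fs_case in list(c("insole", 50), c("platform", 100))) {
    tr <- simulate_pressure_trial(p, "in_device", n_steps = 1,
                                  dialect = fs_case[1],
                                  ppp = 200, pti = oracle(200, 0.6))
    ph <- detect_stance_phases(tr)
    geom <- attr(tr, "geometry")
    mask <- region_mask(geom, sensors = attr(tr, "generation")$mask)
    m <- step_metrics(tr, ph[1, ], mask)
    expect_lt(abs(m$pti - oracle(200, 0.6)) / oracle(200, 0.6), 0.02)
  }
  # near-exact at 10 kHz resampling of the same pulse
  fs <- 10000
  tt <- seq(0, 0.6, by = 1 / fs)
  curve <- 200 * sin(pi * tt / 0.6)
  expect_lt(abs(pracma::trapz(tt, curve) - oracle(200, 0.6)) / oracle(200, 0.6),
            1e-4)
})

test_that("metrics are mask-monotone and scale-equivariant", {
  p <- fixed_profile()
  tr <- simulate_pressure_trial(p, "in_device", n_steps = 6)
  geom <- attr(tr, "geometry")
  ph <- detect_stance_phases(tr)[3, ]
  small <- region_mask(geom, sensors = attr(tr, "generation")$mask[1])
  big <- region_mask(geom, center_mm = c(40, 200), radius_mm = 40)
  m_small <- step_metrics(tr, ph, small)
  m_big <- step_metrics(tr, ph, big)
  expect_gte(m_big$ppp, m_small$ppp)
  expect_gte(m_big$pti, m_small$pti)

  k <- 2.5
  tr_k <- tr
  tr_k[geom$sensor] <- tr_k[geom$sensor] * k
  m1 <- step_metrics(tr, ph, big)
  mk <- step_metrics(tr_k, ph, big)
  expect_equal(mk$ppp, k * m1$ppp)
  expect_equal(mk$pti, k * m1$pti)
})

test_that("trial summaries average per-step and per-trial metrics", {
  # walking: 16 equal rectangles, trim 2 -> mean over 12 equal steps
  s <- rect_series(rep(66.2, 16))
  out <- trial_summary(s, tiny_mask(s), "walking", force_threshold = 5)
  expect_equal(out$n_steps_used, 12)
  expect_equal(out$pti, 66.2)

  # two-step: four single-contact trials averaged
  trials <- lapply(c(400, 500, 600, 480.8), function(p) {
    rect_series(p, contact_s = 1)
  })
  out2 <- trial_summary(trials, tiny_mask(trials[[1]]), "two_step",
                        force_threshold = 5)
  expect_equal(out2$pti, mean(c(400, 500, 600, 480.8)))
  expect_equal(out2$pti, 495.2)
  expect_equal(out2$n_steps_used, 4)

  expect_error(trial_summary(trials[1:3], tiny_mask(trials[[1]]), "two_step"),
               class = "cptstress_error_protocol")
  short <- rect_series(rep(100, 10))
  expect_error(trial_summary(short, tiny_mask(short), "walking"),
               class = "cptstress_error_invalid_trial")
})
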