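#' Ulcer-site region mask
#'
#' Either an explicit set of sensor ids (insole dialect) or all sensors
#' within `radius_mm` of an ulcer coordinate (platform dialect, default
#' radius 10 mm).
#'
#' @param geometry Sensor geometry tibble (`sensor`, `x_mm`, `y_mm`,
#'   `area_cm2`).
#' @param sensors Character vector of sensor ids, or `NULL` to select by
#'   coordinate.
#' @param center_mm Length-2 ulcer coordinate (mm), used when `sensors` is
#'   `NULL`.
#' @param radius_mm Selection radius (mm).
#' @param label Mask label.
#' @return A `region_mask` list with fields `label` and `sensors`.
#' @export
region_mask <- function(geometry, sensors = NULL, center_mm = NULL,
                        radius_mm = 10, label = "ulcer_site") {
  if (is.null(sensors)) {
    if (is.null(center_mm)) {
      abort("supply either `sensors` or `center_mm`", class = "cptstress_error_input")
    }
    d <- sqrt((geometry$x_mm - center_mm[1])^2 + (geometry$y_mm - center_mm[2])^2)
    sensors <- geometry$sensor[d <= radius_mm]
  }
  if (!all(sensors %in% geometry$sensor)) {
    abort("mask sensors must be a subset of the geometry",
          class = "cptstress_error_input")
  }
  if (length(sensors) == 0) {
    abort("region mask is empty", class = "cptstress_error_input")
  }
  structure(list(label = label, sensors = sensors), class = "region_mask")
}

# total vertical force per frame in newtons: sum over sensors of
# pressure (kPa) x area (cm^2) x 0.1 (kPa.cm^2 -> N)
frame_force_n <- function(series) {
  geom <- pf_attr(series, "geometry")
  m <- as.matrix(series[geom$sensor])
  as.vector(m %*% (geom$area_cm2 * 0.1))
}

#' Detect stance phases from total force
#'
#' A stance phase is a maximal run of frames whose total vertical force is
#' at or above `force_threshold` lasting at least `min_duration`. Index
#' intervals are half-open `[start, end)`.
#'
#' @param series A `pressure_frames` series.
#' @param force_threshold Force threshold in N (default 35 N, i.e. 5% of a
#'   700 N body weight).
#' @param min_duration Minimum stance duration in s.
#' @return Tibble `(start, end, duration_s)` of disjoint ordered phases.
#' @export
detect_stance_phases <- function(series, force_threshold = 35, min_duration = 0.1) {
  if (nrow(series) == 0) abort("empty pressure series", class = "cptstress_error_input")
  stopifnot(force_threshold > 0)
  fs <- pf_attr(series, "sampling_rate")
  above <- frame_force_n(series) >= force_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / fs >= min_duration)
  tibble(
    start = starts[keep],
    end = ends[keep] + 1L,            # half-open
    duration_s = r$lengths[keep] / fs
  )
}

#' Select midgait steps
#'
#' Drops the first and last `trim` phases (gait initiation/termination) and
#' requires at least `min_steps` remaining for a valid trial.
#'
#' @param phases Phase tibble from [detect_stance_phases()].
#' @param trim Phases dropped from each end (>= 0).
#' @param min_steps Minimum midgait steps for a valid trial (default 12).
#' @return The retained phases.
#' @export
select_midgait_steps <- function(phases, trim = 2L, min_steps = 12L) {
  stopifnot(trim >= 0)
  n <- nrow(phases)
  kept <- if (n > 2 * trim) phases[seq.int(trim + 1, n - trim), ] else phases[0, ]
  if (nrow(kept) < min_steps) {
    abort(
      sprintf("invalid trial: %d midgait steps after trimming %d of %d (minimum %d)",
              nrow(kept), trim, n, min_steps),
      class = "cptstress_error_invalid_trial",
      n_phases = n, n_midgait = nrow(kept), min_steps = min_steps
    )
  }
  kept
}

#' Peak pressure and pressure-time integral of one stance
#'
#' The regional pressure curve is reduced over the mask sensors per frame
#' (`max` by default, the cluster-peak convention; `mean` is area-weighted).
#' PPP is the curve's maximum over the phase; PTI its trapezoidal integral.
#'
#' @param series A `pressure_frames` series.
#' @param phase One-row phase (`start`, `end`, half-open frame indices).
#' @param mask A [region_mask()].
#' @param reduce `"max"` or `"mean"` across mask sensors per frame.
#' @return Tibble `(ppp, pti)` in kPa and kPa.s.
#' @export
step_metrics <- function(series, phase, mask, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  geom <- pf_attr(series, "geometry")
  if (!all(mask$sensors %in% geom$sensor)) {
    abort("mask is disjoint from the series geometry", class = "cptstress_error_input")
  }
  idx <- seq.int(phase$start, phase$end - 1L)
  if (min(idx) < 1 || max(idx) > nrow(series)) {
    abort("phase lies outside the series", class = "cptstress_error_input")
  }
  m <- as.matrix(series[idx, mask$sensors, drop = FALSE])
  curve <- if (reduce == "max") apply(m, 1, max) else {
    w <- geom$area_cm2[match(mask$sensors, geom$sensor)]
    as.vector(m %*% w) / sum(w)
  }
  tt <- series$time_s[idx]
  tibble(ppp = max(curve),
         pti = if (length(tt) > 1) pracma::trapz(tt, curve) else 0)
}

#' Trial-level pressure summary at the ulcer site
#'
#' Walking protocol: detects stances in one series, keeps the midgait steps
#' and averages per-step PPP and PTI. Two-step protocol: takes exactly four
#' single-contact series (one stance each) and averages the per-trial
#' metrics.
#'
#' @param series A `pressure_frames` series (walking) or a list of exactly
#'   four (two-step).
#' @param mask A [region_mask()].
#' @param protocol `"walking"` or `"two_step"`.
#' @param force_threshold,min_duration Passed to [detect_stance_phases()].
#' @param trim,min_steps Passed to [select_midgait_steps()] (walking only).
#' @param reduce Regional reduction passed to [step_metrics()].
#' @return One-row tibble `(ppp, pti, n_steps_used, protocol)`.
#' @export
trial_summary <- function(series, mask, protocol = c("walking", "two_step"),
                          force_threshold = 35, min_duration = 0.1,
                          trim = 2L, min_steps = 12L, reduce = "max") {
  protocol <- match.arg(protocol)
  if (protocol == "walking") {
    phases <- detect_stance_phases(series, force_threshold, min_duration)
    phases <- select_midgait_steps(phases, trim = trim, min_steps = min_steps)
    per_step <- purrr::map_dfr(seq_len(nrow(phases)), function(i) {
      step_metrics(series, phases[i, ], mask, reduce = reduce)
    })
    tibble(ppp = mean(per_step$ppp), pti = mean(per_step$pti),
           n_steps_used = nrow(per_step), protocol = protocol)
  } else {
    if (!is.list(series) || inherits(series, "pressure_frames") || length(series) != 4) {
      abort("two-step protocol requires exactly 4 single-contact trials",
            class = "cptstress_error_protocol")
    }
    per_trial <- purrr::map_dfr(series, function(s) {
      phases <- detect_stance_phases(s, force_threshold, min_duration)
      if (nrow(phases) < 1) {
        abort("no foot contact found in a two-step trial",
              class = "cptstress_error_invalid_trial")
      }
      # single-contact trial: use the dominant (longest) contact
      ph <- phases[which.max(phases$duration_s), ]
      step_metrics(s, ph, mask, reduce = reduce)
    })
    tibble(ppp = mean(per_trial$ppp), pti = mean(per_trial$pti),
           n_steps_used = nrow(per_trial), protocol = protocol)
  }
}
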