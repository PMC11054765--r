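# Sensor geometries for the two pressure dialects.
#
# Insole dialect: 99 capacitive sensors (11 x 9 grid over a ~250 x 90 mm
# insole), sampled at 50 Hz, worn at the sock-insole interface.
# Platform dialect: a 20 x 10 cell window of a pressure platform with
# 4 sensors/cm^2 (5 mm pitch), sampled at 100 Hz, single foot contact.

#' Sensor geometry for a pressure dialect
#'
#' @param dialect `"insole"` (99 sensors, 50 Hz) or `"platform"`
#'   (5 mm grid, 100 Hz).
#' @return Tibble `(sensor, x_mm, y_mm, area_cm2)`.
#' @export
sensor_geometry <- function(dialect = c("insole", "platform")) {
  dialect <- match.arg(dialect)
  if (dialect == "insole") {
    grid <- expand.grid(col = 0:8, row = 0:10)
    tibble(
      sensor = sprintf("s%03d", seq_len(99)),
      x_mm = grid$col * 10,
      y_mm = grid$row * 25,
      area_cm2 = 2
    )
  } else {
    grid <- expand.grid(col = 0:19, row = 0:9)
    tibble(
      sensor = sprintf("s%03d", seq_len(200)),
      x_mm = grid$col * 5,
      y_mm = grid$row * 5,
      area_cm2 = 0.25
    )
  }
}

dialect_rate <- function(dialect) if (dialect == "insole") 50 else 100

# Default ulcer coordinate per dialect (forefoot for the insole, window
# centre for the platform).
default_ulcer_xy <- function(dialect) {
  if (dialect == "insole") c(40, 200) else c(47.5, 22.5)
}

#' Construct a pressure frame series
#'
#' @param frames Tibble with a `time_s` column plus one column per sensor
#'   (pressures in kPa).
#' @param dialect `"insole"` or `"platform"`.
#' @param sampling_rate Hz.
#' @param geometry Sensor geometry tibble (see [sensor_geometry()]).
#' @return A `pressure_frames` tibble.
#' @export
pressure_frames <- function(frames, dialect, sampling_rate, geometry) {
  sens <- setdiff(names(frames), "time_s")
  if (!setequal(sens, geometry$sensor)) {
    abort("frame columns must match the geometry's sensors",
          class = "cptstress_error_format")
  }
  if (is.unsorted(frames$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing", class = "cptstress_error_format")
  }
  out <- as_tibble(frames)
  attr(out, "dialect") <- dialect
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "geometry") <- geometry
  class(out) <- c("pressure_frames", class(out))
  out
}

pf_attr <- function(series, what) {
  a <- attr(series, what)
  if (is.null(a)) abort(paste0("pressure series lacks `", what, "` attribute"),
                        class = "cptstress_error_format")
  a
}

#' Simulate a plantar pressure trial
#'
#' Builds a walking (insole) or single-contact (platform) trial in which
#' each stance is a half-sine pressure pulse `p(t) = P sin(pi t / T)` on the
#' ulcer-site sensors. `P` is the condition's target peak pressure and `T`
#' is chosen so the analytic per-step pressure-time integral `2 P T / pi`
#' meets the condition's target PTI; `T` is snapped to an even number of
#' samples so the sampled peak equals `P` exactly. Surrounding sensors carry
#' attenuated copies of the pulse so that total force, not just the ulcer
#' site, drives stance detection. The achieved analytic values are stored in
#' the `generation` attribute (the trial's ground truth).
#'
#' @param profile One-row profile with per-condition `ppp_*` / `pti_*`
#'   targets.
#' @param condition `"in_device"` or `"non_device"`.
#' @param n_steps Number of stances (platform trials always have 1).
#' @param dialect `"insole"`, `"platform"`, or `NULL` to infer from the
#'   profile's style (platform for an NL-style non-device trial).
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Gaussian sensor noise SD in kPa (pressures floored at 0).
#' @param ppp,pti Optional explicit targets overriding the profile (kPa,
#'   kPa.s).
#' @return A `pressure_frames` tibble; attribute `generation` holds
#'   `list(ppp, pti, stance_s, n_steps, mask)`.
#' @export
simulate_pressure_trial <- function(profile, condition = c("in_device", "non_device"),
                                    n_steps = 16L, dialect = NULL, seed = 1L,
                                    noise_sd = 0, ppp = NULL, pti = NULL) {
  condition <- match.arg(condition)
  if (is.null(dialect)) {
    dialect <- if (condition == "non_device" && profile$style == "NL") "platform" else "insole"
  }
  fs <- dialect_rate(dialect)
  ppp <- ppp %||% (if (condition == "in_device") profile$ppp_in_device else profile$ppp_non_device)
  pti <- pti %||% (if (condition == "in_device") profile$pti_in_device else profile$pti_non_device)
  if (pti <= 0 || ppp <= 0) {
    abort("target PTI and PPP must be positive", class = "cptstress_error_config")
  }
  if (dialect == "platform") n_steps <- 1L
  stopifnot(n_steps >= 1)

  T_raw <- pti * pi / (2 * ppp)
  T_samp <- max(4L, 2L * round(T_raw * fs / 2))   # even sample count: on-grid peak
  T_stance <- T_samp / fs
  swing <- round(0.4 * fs) / fs
  lead <- round(0.5 * fs) / fs

  geom <- sensor_geometry(dialect)
  ulcer <- default_ulcer_xy(dialect)
  d <- sqrt((geom$x_mm - ulcer[1])^2 + (geom$y_mm - ulcer[2])^2)
  mask_radius <- if (dialect == "insole") 15 else 10
  mask <- geom$sensor[d <= mask_radius]
  halo <- setdiff(geom$sensor[d <= 45], mask)

  total_s <- lead + n_steps * T_stance + (n_steps - 1) * swing + lead
  n_frames <- round(total_s * fs) + 1
  t <- (seq_len(n_frames) - 1) / fs
  pulse <- numeric(n_frames)
  for (k in seq_len(n_steps)) {
    t0 <- lead + (k - 1) * (T_stance + swing)
    idx <- which(t >= t0 - 1e-9 & t <= t0 + T_stance + 1e-9)
    pulse[idx] <- pmax(pulse[idx], sin(pi * (t[idx] - t0) / T_stance))
  }
  pulse[pulse < 1e-12] <- 0

  frames <- matrix(0, nrow = n_frames, ncol = nrow(geom),
                   dimnames = list(NULL, geom$sensor))
  frames[, mask] <- ppp * pulse
  frames[, halo] <- 0.6 * ppp * pulse
  if (noise_sd > 0) {
    withr::local_seed(seed)
    frames <- pmax(frames + rnorm(length(frames), 0, noise_sd), 0)
  }
  out <- pressure_frames(
    dplyr::bind_cols(tibble(time_s = t), as_tibble(frames)),
    dialect = dialect, sampling_rate = fs, geometry = geom
  )
  attr(out, "generation") <- list(
    ppp = ppp, pti = 2 * ppp * T_stance / pi, stance_s = T_stance,
    n_steps = n_steps, mask = mask
  )
  out
}
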