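#' Simulate an in-device temperature log
#'
#' The temperature sensor sits inside the offloading device and samples
#' absolute temperature every 15 minutes. While the device is worn the
#' sensor temperature relaxes first-order toward a skin set-point; off-wear
#' it relaxes toward ambient. The relaxation is integrated exactly across
#' wear-state changes, so the noise-free log is an analytic function of the
#' wear schedule.
#'
#' @param profile One-row profile from [generate_profile()].
#' @param seed Integer seed (used only for the noise draw).
#' @param noise_sd Gaussian measurement noise SD in deg C (>= 0).
#' @param init_temp_c Sensor temperature at the start of the record;
#'   defaults to ambient.
#' @return Tibble `(time, temp_c)` sampled every 15 min over the monitoring
#'   window.
#' @export
simulate_temperature_log <- function(profile, seed = 1L, noise_sd = 0,
                                     init_temp_c = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0", class = "cptstress_error_config")
  wear <- profile_wear_schedule(profile)
  cfg_skin <- attr(profile, "skin_temp_c") %||% 32
  cfg_amb <- attr(profile, "ambient_temp_c") %||% 21
  tau_s <- (attr(profile, "tau_min") %||% 30) * 60
  init <- init_temp_c %||% cfg_amb

  t0 <- as.POSIXct(paste(profile$start_date, "00:00:00"), tz = "UTC")
  t_end <- t0 + profile$monitoring_days * 86400
  samples <- seq(t0, t_end - 900, by = 900)

  # event grid: sample times plus wear-state switch points
  events <- sort(unique(c(as.numeric(samples), as.numeric(wear$on),
                          as.numeric(wear$off), as.numeric(t_end))))
  events <- events[events >= as.numeric(t0) & events <= as.numeric(t_end)]
  worn_at <- in_intervals(as.POSIXct(events, origin = "1970-01-01", tz = "UTC"), wear)

  temp <- numeric(length(events))
  temp[1] <- init
  for (k in seq_along(events)[-1]) {
    dt <- events[k] - events[k - 1]
    target <- if (worn_at[k - 1]) cfg_skin else cfg_amb
    temp[k] <- target + (temp[k - 1] - target) * exp(-dt / tau_s)
  }
  at_samples <- temp[match(as.numeric(samples), events)]

  if (noise_sd > 0) {
    withr::local_seed(seed)
    at_samples <- at_samples + rnorm(length(at_samples), 0, noise_sd)
  }
  tibble(time = samples, temp_c = at_samples)
}

# Place `n` events in bouts inside the given windows. Events within a bout
# are `cadence_s` apart; bout start positions are drawn by distributing the
# free slack uniformly, which keeps bouts disjoint and inside the windows.
place_in_bouts <- function(n, windows, cadence_s, bout_mean) {
  if (n == 0) return(as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"))
  if (nrow(windows) == 0) {
    abort("no placement window available for requested strides",
          class = "cptstress_error_infeasible")
  }
  win <- dplyr::arrange(windows, .data$on)
  len <- as.numeric(win$off) - as.numeric(win$on)
  total <- sum(len)
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, max(1L, rpois(1, bout_mean)))
  excess <- sum(sizes) - n
  if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0]
  nb <- length(sizes)
  occupied <- (sizes - 1) * cadence_s
  slack <- total - sum(occupied) - n * 1e-3
  if (slack <= 0) {
    abort("window too short for requested stride count at this cadence",
          class = "cptstress_error_infeasible")
  }
  g <- runif(nb + 1)
  gaps <- g / sum(g) * slack
  starts_virtual <- cumsum(gaps)[seq_len(nb)] + c(0, cumsum(occupied))[seq_len(nb)]
  v <- unlist(purrr::map2(starts_virtual, sizes, function(s, b) s + (seq_len(b) - 1) * cadence_s))
  # map virtual position in [0, total) onto the concatenated windows
  cum_start <- c(0, cumsum(len))
  idx <- findInterval(v, cum_start, rightmost.closed = TRUE)
  idx[idx > nrow(win)] <- nrow(win)
  times <- as.numeric(win$on)[idx] + (v - cum_start[idx])
  sort(as.POSIXct(times, origin = "1970-01-01", tz = "UTC"))
}

#' Simulate a stride-event stream
#'
#' Draws a daily stride count around the profile's true mean (Poisson), and
#' places strides in walking bouts. Each day, a fraction equal to the
#' profile's true adherence (rounded to the nearest stride) falls inside the
#' device-wear schedule; the rest fall in waking hours outside it. No
#' strides occur at night.
#'
#' @param profile One-row profile from [generate_profile()].
#' @param seed Integer seed.
#' @param config The [synth_config()] used for bout structure and waking
#'   hours (defaults match [generate_profile()]'s defaults).
#' @return Tibble `(time, day, in_wear_truth)` of stride timestamps, with
#'   attribute `source = "simulated"`.
#' @export
simulate_stride_stream <- function(profile, seed = 1L, config = synth_config()) {
  wear <- profile_wear_schedule(profile)
  if (nrow(wear) == 0 && profile$true_adherence > 0) {
    abort("empty wear schedule with positive true adherence is infeasible",
          class = "cptstress_error_infeasible")
  }
  withr::local_seed(seed)
  days <- profile$start_date + seq_len(profile$monitoring_days) - 1
  out <- purrr::map_dfr(seq_along(days), function(d) {
    midnight <- as.POSIXct(paste(days[d], "00:00:00"), tz = "UTC")
    day_start <- midnight + config$active_hours[1] * 3600
    day_end <- midnight + config$active_hours[2] * 3600
    wear_d <- clip_intervals(wear, day_start, day_end)
    nonwear_d <- complement_intervals(wear_d, day_start, day_end)
    # 1 s margin at window edges keeps cross-class stride gaps realistic
    wear_d <- inset_intervals(wear_d, 1)
    nonwear_d <- inset_intervals(nonwear_d, 1)
    n_d <- rpois(1, profile$true_daily_strides)
    n_in <- round(profile$true_adherence * n_d)
    t_in <- place_in_bouts(n_in, wear_d, config$cadence_s, config$bout_mean_strides)
    t_out <- place_in_bouts(n_d - n_in, nonwear_d, config$cadence_s,
                            config$bout_mean_strides)
    tibble(
      time = c(t_in, t_out),
      day = days[d],
      in_wear_truth = rep(c(TRUE, FALSE), c(length(t_in), length(t_out)))
    ) |> dplyr::arrange(.data$time)
  })
  attr(out, "source") <- "simulated"
  out
}

#' Simulate a trunk acceleration record from stride events
#'
#' The vertical channel carries baseline gravity (1 g) plus noise, with one
#' dominant half-sine peak centred on each stride timestamp. Samples are
#' clipped to the +/- 6 g sensor range. Optional non-wear windows are
#' rendered as constant gravity with no noise (near-zero variance).
#'
#' @param strides Tibble with a POSIXct `time` column (may have 0 rows).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Baseline accelerometer noise SD in g.
#' @param stride_amp_g Peak amplitude added at each stride (g).
#' @param stride_dur_s Width of the stride peak (s).
#' @param start,end Record window (POSIXct); defaults to the stride range
#'   padded by 5 s. Required when `strides` is empty.
#' @param nonwear Optional interval tibble (`on`, `off`) of device non-wear.
#' @return Tibble `(time, ax_g, ay_g, az_g)` with attributes
#'   `sampling_rate` and `start`.
#' @export
simulate_acceleration <- function(strides, sampling_rate = 100, seed = 1L,
                                  noise_sd = 0.02, stride_amp_g = 1.2,
                                  stride_dur_s = 0.3, start = NULL, end = NULL,
                                  nonwear = NULL) {
  stopifnot(sampling_rate > 0)
  if (nrow(strides) == 0 && (is.null(start) || is.null(end))) {
    abort("`start` and `end` are required when there are no strides",
          class = "cptstress_error_input")
  }
  start <- start %||% (min(strides$time) - 5)
  end <- end %||% (max(strides$time) + 5)
  withr::local_seed(seed)
  n <- floor(as.numeric(end - start, units = "secs") * sampling_rate)
  t_rel <- (seq_len(n) - 1) / sampling_rate
  az <- 1 + rnorm(n, 0, noise_sd)
  ax <- rnorm(n, 0, noise_sd / 2)
  ay <- rnorm(n, 0, noise_sd / 2)
  s_rel <- as.numeric(strides$time) - as.numeric(start)
  for (s in s_rel) {
    lo <- s - stride_dur_s / 2
    idx <- which(t_rel >= lo & t_rel <= s + stride_dur_s / 2)
    az[idx] <- az[idx] + stride_amp_g * sin(pi * (t_rel[idx] - lo) / stride_dur_s)
  }
  times <- start + t_rel
  if (!is.null(nonwear) && nrow(nonwear) > 0) {
    off <- in_intervals(times, nonwear)
    az[off] <- 1; ax[off] <- 0; ay[off] <- 0
  }
  clip <- function(x) pmin(pmax(x, -6), 6)
  out <- tibble(time = times, ax_g = clip(ax), ay_g = clip(ay), az_g = clip(az))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "start") <- start
  out
}

#' Simulate a thermal image pair (region-of-interest means)
#'
#' Produces pre/post-walk plantar temperatures at the ulcer site (index
#' foot) and the mirrored contralateral location such that the thermal
#' stress response evaluated on them equals the profile's target for the
#' condition exactly in noise-free mode.
#'
#' @param profile One-row profile carrying `tsr_in_device` /
#'   `tsr_non_device` targets.
#' @param condition `"in_device"` or `"non_device"`.
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Gaussian noise SD (deg C) added to each reading.
#' @param contra_pre Contralateral pre-walk temperature (deg C).
#' @param contra_rel_change Relative pre-to-post change of the contralateral
#'   foot; must be non-zero for a finite target.
#' @return One-row tibble `(condition, index_pre, index_post, contra_pre,
#'   contra_post)` in deg C.
#' @export
simulate_thermal_pair <- function(profile, condition = c("in_device", "non_device"),
                                  seed = 1L, noise_sd = 0, contra_pre = 30,
                                  contra_rel_change = 0.05) {
  condition <- match.arg(condition)
  target <- if (condition == "in_device") profile$tsr_in_device else profile$tsr_non_device
  if (is.na(target)) {
    abort("profile carries no thermal stress response target for this condition",
          class = "cptstress_error_input")
  }
  if (contra_rel_change == 0 && is.finite(target)) {
    abort("zero contralateral change cannot realise a finite target",
          class = "cptstress_error_infeasible")
  }
  index_pre <- contra_pre
  pair <- tibble(
    condition = condition,
    index_pre = index_pre,
    index_post = index_pre * (1 + contra_rel_change * target),
    contra_pre = contra_pre,
    contra_post = contra_pre * (1 + contra_rel_change)
  )
  if (noise_sd > 0) {
    withr::local_seed(seed)
    pair[2:5] <- purrr::map(pair[2:5], ~ .x + rnorm(1, 0, noise_sd))
  }
  pair
}
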