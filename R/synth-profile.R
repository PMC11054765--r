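#' Draw one synthetic participant profile
#'
#' A profile holds the ground-truth parameters of one synthetic participant:
#' true adherence (fraction of strides taken in the offloading device), the
#' mean of the daily stride-count distribution, per-condition PTI and PPP
#' targets, per-condition thermal stress response targets (AU style only),
#' the daily device wear schedule, and the healed outcome label.
#'
#' @param seed Integer seed; identical seed and config give an identical
#'   profile.
#' @param config A [synth_config()].
#' @param id Participant identifier.
#' @return One-row tibble (a `participant_profile`).
#' @examples
#' generate_profile(seed = 1)
#' @export
generate_profile <- function(seed, config = synth_config(), id = "P01") {
  validate_synth_config(config)
  withr::local_seed(seed)
  draw <- function(r) runif(1, r[1], r[2])
  healed <- runif(1) < config$healed_fraction
  strides_mean <- draw(config$daily_strides_range)
  if (healed) strides_mean <- strides_mean * config$healed_activity_factor
  wear_on <- draw(config$wear_on_range)
  wear_off <- draw(config$wear_off_range)
  prof <- tibble(
    id = id,
    style = config$style,
    true_adherence = draw(config$adherence_range),
    true_daily_strides = max(1, round(strides_mean)),
    pti_in_device = draw(config$pti_in_range),
    pti_non_device = draw(config$pti_non_range),
    ppp_in_device = draw(config$ppp_in_range),
    ppp_non_device = draw(config$ppp_non_range),
    tsr_in_device = if (config$style == "AU") draw(config$tsr_in_range) else NA_real_,
    tsr_non_device = if (config$style == "AU") draw(config$tsr_non_range) else NA_real_,
    wear_on_h = wear_on,
    wear_off_h = wear_off,
    monitor_on_h = config$monitor_on_hour,
    monitor_wear_h = draw(config$monitor_wear_hours_range),
    monitoring_days = config$monitoring_days,
    start_date = config$start_date,
    healed = healed
  )
  class(prof) <- c("participant_profile", class(prof))
  prof
}

#' Draw a cohort of synthetic participant profiles
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer master seed; per-participant seeds are derived from it.
#' @param config A [synth_config()]; for a mixed cohort see
#'   [generate_cohort()]'s `n_nl` argument.
#' @return Tibble with one row per participant.
#' @export
cohort_profiles <- function(n, seed, config = synth_config()) {
  stopifnot(n >= 1)
  purrr::map_dfr(seq_len(n), function(i) {
    generate_profile(derive_seed(seed, i), config, id = sprintf("P%02d", i))
  })
}

# Daily device-wear schedule of a profile as an interval set over its
# monitoring window (one wear block per day).
profile_wear_schedule <- function(profile) {
  days <- profile$start_date + seq_len(profile$monitoring_days) - 1
  midnight <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC")
  new_interval_set(midnight + profile$wear_on_h * 3600,
                   midnight + profile$wear_off_h * 3600)
}

# Daily activity-monitor wear intervals (the trunk accelerometer, not the
# offloading device).
profile_monitor_schedule <- function(profile) {
  days <- profile$start_date + seq_len(profile$monitoring_days) - 1
  midnight <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC")
  on <- midnight + profile$monitor_on_h * 3600
  off <- on + profile$monitor_wear_h * 3600
  new_interval_set(on, off)
}
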