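#' Configuration for the synthetic cohort generator
#'
#' Defines the generative conditions for a synthetic cohort of people with a
#' plantar foot ulcer treated with a removable offloading device. Default
#' ranges are the interquartile ranges of the corresponding observed cohort
#' quantities: adherence 26.6--68.7% of strides in device, 1015--12456
#' strides/day, in-device PTI 60.0--74.7 kPa.s and PPP 110.9--302.7 kPa,
#' footwear (non-device, in-shoe style) PTI 67.2--86.3 kPa.s and PPP
#' 141.4--236.4 kPa, barefoot (non-device, platform style) PTI 235.7--626.1
#' kPa.s and PPP 446.0--923.8 kPa, thermal stress response 0.30--1.07
#' (in-device) and -0.15--2.54 (non-device). Draws are uniform on each range.
#'
#' `style` selects the non-device pressure protocol and thermal availability:
#' `"AU"` measures the non-device condition in regular footwear with the
#' insole system and includes thermography; `"NL"` measures it barefoot on a
#' pressure platform with the 2-step protocol and has no thermography.
#'
#' `healed_fraction` of participants are labelled healed; their stride-count
#' mean is scaled by `healed_activity_factor` so that healed participants
#' carry lower cumulative stress, mirroring the direction of the clinical
#' observation the generator emulates.
#'
#' @param style `"AU"` or `"NL"`.
#' @param adherence_range Fraction of strides taken in-device, `[0,1]`.
#' @param daily_strides_range Mean strides/day range (positive).
#' @param pti_in_range,ppp_in_range In-device PTI (kPa.s) / PPP (kPa) range.
#' @param pti_non_range,ppp_non_range Non-device ranges; defaults depend on
#'   `style` (footwear for AU, barefoot for NL).
#' @param tsr_in_range,tsr_non_range Thermal stress response ranges
#'   (dimensionless); ignored for NL style.
#' @param monitoring_days Days of monitoring (>= 6).
#' @param wear_on_range,wear_off_range Daily device on/off clock time ranges
#'   in hours (device worn in one daily block).
#' @param monitor_wear_hours_range Daily activity-monitor wear duration range
#'   (hours), starting at `monitor_on_hour`.
#' @param monitor_on_hour Clock hour the activity monitor goes on.
#' @param active_hours Waking window `[start, end)` in clock hours within
#'   which strides may occur (no strides at night).
#' @param healed_fraction Fraction of participants labelled healed.
#' @param healed_activity_factor Multiplier on healed participants'
#'   stride-count mean.
#' @param skin_temp_c,ambient_temp_c,tau_min In-device temperature model:
#'   set-points (deg C) and first-order time constant (minutes).
#' @param bout_mean_strides Mean strides per walking bout.
#' @param cadence_s Seconds per stride within a bout.
#' @param stance_swing_s Swing time between stances in a pressure trial (s).
#' @param start_date First monitoring day (UTC).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(style = c("AU", "NL"),
                         adherence_range = c(0.266, 0.687),
                         daily_strides_range = c(1015, 12456),
                         pti_in_range = c(60.0, 74.7),
                         ppp_in_range = c(110.9, 302.7),
                         pti_non_range = NULL,
                         ppp_non_range = NULL,
                         tsr_in_range = c(0.30, 1.07),
                         tsr_non_range = c(-0.15, 2.54),
                         monitoring_days = 7L,
                         wear_on_range = c(7, 9),
                         wear_off_range = c(19, 21),
                         monitor_wear_hours_range = c(13, 16),
                         monitor_on_hour = 6.5,
                         active_hours = c(6, 23),
                         healed_fraction = 0.5,
                         healed_activity_factor = 0.5,
                         skin_temp_c = 32,
                         ambient_temp_c = 21,
                         tau_min = 30,
                         bout_mean_strides = 30,
                         cadence_s = 1.1,
                         stance_swing_s = 0.4,
                         start_date = as.Date("2023-05-01")) {
  style <- match.arg(style)
  if (is.null(pti_non_range)) {
    pti_non_range <- if (style == "AU") c(67.2, 86.3) else c(235.7, 626.1)
  }
  if (is.null(ppp_non_range)) {
    ppp_non_range <- if (style == "AU") c(141.4, 236.4) else c(446.0, 923.8)
  }
  cfg <- list(
    style = style,
    adherence_range = adherence_range,
    daily_strides_range = daily_strides_range,
    pti_in_range = pti_in_range, ppp_in_range = ppp_in_range,
    pti_non_range = pti_non_range, ppp_non_range = ppp_non_range,
    tsr_in_range = tsr_in_range, tsr_non_range = tsr_non_range,
    monitoring_days = as.integer(monitoring_days),
    wear_on_range = wear_on_range, wear_off_range = wear_off_range,
    monitor_wear_hours_range = monitor_wear_hours_range,
    monitor_on_hour = monitor_on_hour,
    active_hours = active_hours,
    healed_fraction = healed_fraction,
    healed_activity_factor = healed_activity_factor,
    skin_temp_c = skin_temp_c, ambient_temp_c = ambient_temp_c,
    tau_min = tau_min,
    bout_mean_strides = bout_mean_strides, cadence_s = cadence_s,
    stance_swing_s = stance_swing_s,
    start_date = as.Date(start_date)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  rng <- function(name) {
    r <- cfg[[name]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      abort(paste0("invalid range in `", name, "`: min must not exceed max"),
            class = "cptstress_error_config")
    }
  }
  for (nm in c("adherence_range", "daily_strides_range", "pti_in_range",
               "ppp_in_range", "pti_non_range", "ppp_non_range",
               "tsr_in_range", "tsr_non_range", "wear_on_range",
               "wear_off_range", "monitor_wear_hours_range", "active_hours")) {
    rng(nm)
  }
  if (cfg$adherence_range[1] < 0 || cfg$adherence_range[2] > 1) {
    abort("`adherence_range` must lie in [0, 1]", class = "cptstress_error_config")
  }
  if (cfg$pti_in_range[1] <= 0 || cfg$pti_non_range[1] <= 0 ||
      cfg$ppp_in_range[1] <= 0 || cfg$ppp_non_range[1] <= 0) {
    abort("PTI and PPP ranges must be strictly positive",
          class = "cptstress_error_config")
  }
  if (cfg$monitoring_days < 6L) {
    abort("`monitoring_days` must be at least 6", class = "cptstress_error_config")
  }
  invisible(cfg)
}

# deterministic per-participant sub-seed, kept within 32-bit integer range
derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 7919 + i * 104729 + salt * 15485863) %% 2147483647)
}
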