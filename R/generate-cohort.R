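#' Generate a synthetic cohort on disk with a ground-truth manifest
#'
#' Writes, per participant, the sensor streams the pipeline consumes --
#' in-device and non-device pressure trials (walking insole trials for AU
#' style; four single-contact platform trials for NL style), stride events,
#' activity-monitor wear intervals, the in-device temperature log, and (AU
#' style) thermal reading pairs -- plus a cohort `manifest.json` holding
#' every participant's true parameters, the realised per-day stride truth,
#' and the analytic CPTS each participant's streams encode. The manifest is
#' what parameter-recovery tests compare against.
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer master seed; the run is deterministic given
#'   `(seed, config)`.
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()] for the AU-style participants.
#' @param n_nl How many of the `n` participants are NL-style (no thermal
#'   stream, platform barefoot non-device pressure); they are the last
#'   `n_nl` ids.
#' @param temp_noise_sd Temperature-log noise SD in deg C.
#' @param pressure_noise_sd Pressure-frame noise SD in kPa.
#' @param n_steps Stances per walking pressure trial.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
generate_cohort <- function(n, seed, dir, config = synth_config(), n_nl = 0,
                            temp_noise_sd = 0.3, pressure_noise_sd = 0,
                            n_steps = 16L) {
  stopifnot(n >= 1, n_nl >= 0, n_nl <= n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create output directory: ", dir),
          class = "cptstress_error_io")
  }
  cfg_nl <- config
  cfg_nl$style <- "NL"
  cfg_nl$pti_non_range <- c(235.7, 626.1)
  cfg_nl$ppp_non_range <- c(446.0, 923.8)

  participants <- purrr::map(seq_len(n), function(i) {
    cfg <- if (i > n - n_nl) cfg_nl else config
    id <- sprintf("P%02d", i)
    prof <- generate_profile(derive_seed(seed, i), cfg, id = id)
    pdir <- file.path(dir, id)
    dir.create(pdir, showWarnings = FALSE)

    strides <- simulate_stride_stream(prof, derive_seed(seed, i, 1L), cfg)
    write_strides_csv(strides, file.path(pdir, "strides.csv"))
    write_intervals_csv(profile_monitor_schedule(prof),
                        file.path(pdir, "monitor_wear.csv"))
    temp_log <- simulate_temperature_log(prof, derive_seed(seed, i, 2L),
                                         noise_sd = temp_noise_sd)
    write_temperature_csv(temp_log, file.path(pdir, "temperature.csv"))

    p_in <- simulate_pressure_trial(prof, "in_device", n_steps = n_steps,
                                    seed = derive_seed(seed, i, 3L),
                                    noise_sd = pressure_noise_sd)
    write_pressure_csv(p_in, file.path(pdir, "pressure_in_device.csv"))
    pressure_non_files <- if (prof$style == "AU") {
      p_non <- simulate_pressure_trial(prof, "non_device", n_steps = n_steps,
                                       seed = derive_seed(seed, i, 4L),
                                       noise_sd = pressure_noise_sd)
      write_pressure_csv(p_non, file.path(pdir, "pressure_non_device.csv"))
      "pressure_non_device.csv"
    } else {
      p_non <- simulate_pressure_trial(prof, "non_device", dialect = "platform",
                                       seed = derive_seed(seed, i, 4L),
                                       noise_sd = pressure_noise_sd)
      purrr::map_chr(1:4, function(k) {
        f <- sprintf("pressure_non_device_trial%d.csv", k)
        write_pressure_csv(p_non, file.path(pdir, f))
        f
      })
    }
    if (prof$style == "AU") {
      pairs <- dplyr::bind_rows(
        simulate_thermal_pair(prof, "in_device", derive_seed(seed, i, 5L)),
        simulate_thermal_pair(prof, "non_device", derive_seed(seed, i, 6L))
      )
      write_thermal_json(pairs, file.path(pdir, "thermal.json"))
    }

    # realised ground truth: per-day counts and the analytic CPTS the
    # streams encode (valid day = monitor wear >= 12 h)
    monitor <- profile_monitor_schedule(prof)
    daily <- strides |>
      dplyr::summarise(
        strides_in = sum(.data$in_wear_truth),
        strides_non = sum(!.data$in_wear_truth),
        .by = "day"
      )
    valid_dates <- utc_day(monitor$on)[interval_hours_by_row(monitor) >= 12]
    daily$valid <- daily$day %in% valid_dates
    pti_in_true <- attr(p_in, "generation")$pti
    pti_non_true <- attr(p_non, "generation")$pti
    vd <- daily[daily$valid, ]
    cpts1 <- mean(cpts_day_model1(pti_in_true, pti_non_true,
                                  vd$strides_in, vd$strides_non))
    cpts2 <- if (prof$style == "AU") {
      mean(cpts_day_model2(pti_in_true, pti_non_true, vd$strides_in,
                           vd$strides_non, prof$tsr_in_device,
                           prof$tsr_non_device))
    } else NA_real_

    list(
      profile = prof,
      daily_truth = daily,
      truth = tibble(
        id = id, style = prof$style,
        adherence_realised = 100 * sum(vd$strides_in) /
          (sum(vd$strides_in) + sum(vd$strides_non)),
        mean_strides_per_day = mean(vd$strides_in + vd$strides_non),
        pti_in = pti_in_true, pti_non = pti_non_true,
        ppp_in = attr(p_in, "generation")$ppp,
        ppp_non = attr(p_non, "generation")$ppp,
        tsr_in = prof$tsr_in_device, tsr_non = prof$tsr_non_device,
        cpts_model1 = cpts1, cpts_model2 = cpts2,
        n_valid_days = nrow(vd), healed = prof$healed
      ),
      files = list(
        strides = "strides.csv", monitor_wear = "monitor_wear.csv",
        temperature = "temperature.csv",
        pressure_in = "pressure_in_device.csv",
        pressure_non = pressure_non_files,
        thermal = if (prof$style == "AU") "thermal.json" else NULL
      )
    )
  })

  manifest <- list(
    seed = seed,
    config_digest = rlang::hash(list(config, n, n_nl, temp_noise_sd,
                                     pressure_noise_sd, n_steps)),
    n = n, n_nl = n_nl,
    profiles = purrr::map_dfr(participants, function(p) {
      prof <- p$profile
      prof$start_date <- as.character(prof$start_date)
      prof
    }),
    truth = purrr::map_dfr(participants, "truth"),
    daily_truth = purrr::map_dfr(participants, function(p) {
      dplyr::mutate(p$daily_truth, id = p$profile$id, day = as.character(.data$day))
    }),
    files = setNames(purrr::map(participants, "files"),
                     purrr::map_chr(participants, ~ .x$profile$id))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

interval_hours_by_row <- function(intervals) {
  (as.numeric(intervals$off) - as.numeric(intervals$on)) / 3600
}

#' Read a cohort manifest back from disk
#'
#' @param dir Cohort directory written by [generate_cohort()].
#' @return The manifest list with `profiles`, `truth` and `daily_truth` as
#'   tibbles.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    abort(paste0("no manifest.json in ", dir), class = "cptstress_error_io")
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$profiles <- as_tibble(m$profiles)
  m$profiles$start_date <- as.Date(m$profiles$start_date)
  m$truth <- as_tibble(m$truth)
  m$daily_truth <- as_tibble(m$daily_truth)
  m$daily_truth$day <- as.Date(m$daily_truth$day)
  m
}
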