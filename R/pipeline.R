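#' Pipeline configuration
#'
#' Algorithm parameters for every stage of the per-participant pipeline,
#' with the package defaults. `style` controls whether the non-device
#' pressure source is a walking insole trial in regular footwear (`"AU"`)
#' or four barefoot single-contact platform trials (`"NL"`), and whether a
#' thermal stream (and hence CPTS model 2) is expected.
#'
#' @param style `"AU"` or `"NL"`.
#' @param force_threshold_n,min_stance_s Stance detection parameters.
#' @param trim_steps,min_midgait_steps Midgait selection parameters.
#' @param regional_reduce `"max"` (cluster peak) or `"mean"`.
#' @param ulcer_center_mm,ulcer_radius_mm Ulcer-site mask definition; `NULL`
#'   centre uses the dialect default.
#' @param wear_on_c,wear_off_c,wear_min_slope_c,wear_fall_slope_c
#'   Temperature wear-detection parameters (deg C, deg C/sample).
#' @param min_wear_h,min_valid_days Valid-day rule.
#' @return A list of class `study_config`.
#' @export
study_config <- function(style = c("AU", "NL"),
                         force_threshold_n = 35, min_stance_s = 0.1,
                         trim_steps = 2L, min_midgait_steps = 12L,
                         regional_reduce = "max",
                         ulcer_center_mm = NULL, ulcer_radius_mm = 15,
                         wear_on_c = 27, wear_off_c = 25,
                         wear_min_slope_c = 0.5, wear_fall_slope_c = 2,
                         min_wear_h = 12, min_valid_days = 4L) {
  style <- match.arg(style)
  structure(list(
    style = style,
    force_threshold_n = force_threshold_n, min_stance_s = min_stance_s,
    trim_steps = trim_steps, min_midgait_steps = min_midgait_steps,
    regional_reduce = regional_reduce,
    ulcer_center_mm = ulcer_center_mm, ulcer_radius_mm = ulcer_radius_mm,
    wear_on_c = wear_on_c, wear_off_c = wear_off_c,
    wear_min_slope_c = wear_min_slope_c, wear_fall_slope_c = wear_fall_slope_c,
    min_wear_h = min_wear_h, min_valid_days = min_valid_days
  ), class = "study_config")
}

pipeline_mask <- function(series, config) {
  geom <- pf_attr(series, "geometry")
  center <- config$ulcer_center_mm %||% default_ulcer_xy(pf_attr(series, "dialect"))
  radius <- if (pf_attr(series, "dialect") == "platform") 10 else config$ulcer_radius_mm
  region_mask(geom, center_mm = center, radius_mm = radius)
}

# classify an error condition into the completion-reason taxonomy
status_of_error <- function(cnd) {
  if (inherits(cnd, "cptstress_error_non_adherent")) "non_adherent" else "technical"
}

run_factor <- function(expr) {
  tryCatch(
    list(status = "complete", value = suppressWarnings(expr), detail = NA_character_),
    error = function(e) list(status = status_of_error(e), value = NULL,
                             detail = conditionMessage(e))
  )
}

#' Run the CPTS pipeline for one participant
#'
#' Executes pressure, activity, adherence and (for AU style) thermal
#' processing on a participant's stream files and fuses them into CPTS.
#' A failing factor never aborts the run: it yields a per-factor completion
#' status from the closed reason taxonomy (complete, non-adherent,
#' technical, combination), and CPTS is marked incomplete.
#'
#' @param bundle List with `id`, `dir`, and `files` (named paths relative
#'   to `dir`: `pressure_in`, `pressure_non` (one or four files),
#'   `strides` or `acceleration`, `monitor_wear` (optional with
#'   acceleration), `temperature`, `thermal` (AU)); optionally `healed`.
#' @param config A [study_config()].
#' @return List of class `participant_result`: `id`, `status` (overall),
#'   `factors` tibble, `measures` one-row tibble, `cpts`
#'   ([cpts_result()] or `NULL`), `healed`.
#' @export
run_participant <- function(bundle, config = study_config()) {
  path_of <- function(f) file.path(bundle$dir, f)
  f <- bundle$files

  press_in <- run_factor({
    s <- read_stream(path_of(f$pressure_in), "pressure")
    trial_summary(s, pipeline_mask(s, config), "walking",
                  force_threshold = config$force_threshold_n,
                  min_duration = config$min_stance_s,
                  trim = config$trim_steps, min_steps = config$min_midgait_steps,
                  reduce = config$regional_reduce)
  })
  press_non <- run_factor({
    paths <- path_of(f$pressure_non)
    if (length(paths) == 1) {
      s <- read_stream(paths, "pressure")
      trial_summary(s, pipeline_mask(s, config), "walking",
                    force_threshold = config$force_threshold_n,
                    min_duration = config$min_stance_s,
                    trim = config$trim_steps, min_steps = config$min_midgait_steps,
                    reduce = config$regional_reduce)
    } else {
      trials <- purrr::map(paths, read_stream, kind = "pressure")
      trial_summary(trials, pipeline_mask(trials[[1]], config), "two_step",
                    force_threshold = config$force_threshold_n,
                    min_duration = config$min_stance_s,
                    reduce = config$regional_reduce)
    }
  })

  activity <- run_factor({
    strides <- if (!is.null(f$strides)) {
      read_stream(path_of(f$strides), "strides")
    } else {
      detect_strides(read_stream(path_of(f$acceleration), "acceleration"))
    }
    wear <- if (!is.null(f$monitor_wear)) {
      read_stream(path_of(f$monitor_wear), "intervals")
    } else {
      detect_monitor_wear(read_stream(path_of(f$acceleration), "acceleration"))
    }
    daily <- daily_activity(strides, wear, min_wear_h = config$min_wear_h,
                            min_valid_days = config$min_valid_days)
    list(strides = strides, daily = daily,
         mean_strides = attr(daily, "mean_strides_per_day"),
         valid_dates = daily$date[daily$valid])
  })

  adher <- run_factor({
    if (activity$status != "complete") {
      # inherit the blocking factor's reason so the taxonomy stays truthful
      abort("adherence needs valid activity data",
            class = if (activity$status == "non_adherent")
              "cptstress_error_non_adherent" else "cptstress_error_input")
    }
    log <- read_stream(path_of(f$temperature), "temperature")
    wear <- wear_intervals_from_temperature(
      log, on_threshold = config$wear_on_c, off_threshold = config$wear_off_c,
      min_slope = config$wear_min_slope_c, fall_slope = config$wear_fall_slope_c
    )
    counts <- classify_strides(activity$value$strides, wear,
                               coverage = range(log$time))
    list(counts = counts,
         summary = adherence_percent(counts, activity$value$valid_dates))
  })

  thermal <- if (config$style == "AU") {
    run_factor({
      pairs <- read_stream(path_of(f$thermal), "thermal")
      purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
        thermal_stress_response(pairs[i, ])
      })
    })
  } else {
    list(status = "not_measured", value = NULL, detail = "no thermal camera")
  }

  cpts <- NULL
  core_ok <- press_in$status == "complete" && press_non$status == "complete" &&
    activity$status == "complete" && adher$status == "complete"
  if (core_ok) {
    tsr_in <- tsr_non <- NULL
    if (identical(thermal$status, "complete")) {
      tv <- thermal$value
      tsr_in <- tv$tsr[tv$condition == "in_device"][1]
      tsr_non <- tv$tsr[tv$condition == "non_device"][1]
    }
    cpts <- cpts_result(adher$value$counts,
                        pti_in = press_in$value$pti,
                        pti_non = press_non$value$pti,
                        tsr_in = tsr_in, tsr_non = tsr_non,
                        valid_dates = activity$value$valid_dates)
  }

  factors <- tibble(
    factor = c("pressure_in_device", "pressure_non_device", "activity",
               "adherence", "thermal"),
    status = c(press_in$status, press_non$status, activity$status,
               adher$status, thermal$status),
    detail = c(press_in$detail, press_non$detail, activity$detail,
               adher$detail, thermal$detail)
  )
  fs <- factors$status[factors$status != "not_measured"]
  overall <- if (all(fs == "complete")) "complete"
  else if (all(fs %in% c("complete", "technical"))) "technical"
  else if (all(fs %in% c("complete", "non_adherent"))) "non_adherent"
  else "combination"

  measures <- tibble(
    id = bundle$id,
    pti_in = press_in$value$pti %||% NA_real_,
    ppp_in = press_in$value$ppp %||% NA_real_,
    pti_non = press_non$value$pti %||% NA_real_,
    ppp_non = press_non$value$ppp %||% NA_real_,
    mean_strides_per_day = activity$value$mean_strides %||% NA_real_,
    adherence_percent = if (adher$status == "complete")
      adher$value$summary$adherence_percent else NA_real_,
    tsr_in = if (identical(thermal$status, "complete"))
      thermal$value$tsr[thermal$value$condition == "in_device"][1] else NA_real_,
    tsr_non = if (identical(thermal$status, "complete"))
      thermal$value$tsr[thermal$value$condition == "non_device"][1] else NA_real_,
    cpts_model1 = if (!is.null(cpts)) cpts$summary_model1 else NA_real_,
    cpts_model2 = if (!is.null(cpts)) cpts$summary_model2 else NA_real_,
    n_valid_days = if (!is.null(cpts)) cpts$n_valid_days else NA_integer_,
    status = overall,
    healed = bundle$healed %||% NA
  )
  structure(list(id = bundle$id, status = overall, factors = factors,
                 measures = measures, cpts = cpts,
                 healed = bundle$healed %||% NA),
            class = "participant_result")
}

#' @export
print.participant_result <- function(x, ...) {
  cat("Participant", x$id, "-", x$status, "\n")
  print(x$factors)
  if (!is.null(x$cpts)) print(x$cpts)
  invisible(x)
}

#' Run the CPTS pipeline over a cohort directory
#'
#' Processes every participant in a cohort written by [generate_cohort()]
#' (or laid out the same way), then compares CPTS and every underlying
#' factor between healed and non-healed participants (median with
#' interquartile range, Mann-Whitney p, effect size r) and tallies
#' completion statuses.
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @param config A [study_config()]; `NULL` derives the style per
#'   participant from the manifest.
#' @param stage Label for the feasibility tally (default `"baseline"`).
#' @return List of class `cohort_report`: `participants` (results),
#'   `measures` tibble, `comparison` tibble (healed vs non-healed),
#'   `feasibility` tally tibble.
#' @export
run_cohort <- function(dir, config = NULL, stage = "baseline") {
  manifest <- read_manifest(dir)
  ids <- names(manifest$files)
  if (length(ids) < 2) {
    abort("a cohort needs at least 2 participants", class = "cptstress_error_input")
  }
  results <- purrr::map(ids, function(id) {
    prof <- manifest$profiles[manifest$profiles$id == id, ]
    cfg <- config %||% study_config(style = prof$style)
    files <- manifest$files[[id]]
    files$pressure_non <- unlist(files$pressure_non)
    run_participant(
      list(id = id, dir = file.path(dir, id), files = files,
           healed = prof$healed),
      cfg
    )
  })
  measures <- purrr::map_dfr(results, "measures")

  comparison <- compare_groups(measures)
  feasibility <- feasibility_tally(
    tibble(id = measures$id, stage = stage, status = measures$status)
  )
  structure(list(participants = results, measures = measures,
                 comparison = comparison, feasibility = feasibility),
            class = "cohort_report")
}

# healed vs non-healed comparison for each numeric outcome: median [IQR]
# per group, Mann-Whitney p and effect size r. Skipped (with a notice)
# when a group is empty.
compare_groups <- function(measures) {
  vars <- c("cpts_model1", "cpts_model2", "pti_in", "ppp_in", "pti_non",
            "ppp_non", "mean_strides_per_day", "adherence_percent",
            "tsr_in", "tsr_non")
  healed <- measures[measures$healed %in% TRUE, ]
  non <- measures[measures$healed %in% FALSE, ]
  if (nrow(healed) == 0 || nrow(non) == 0) {
    inform("fewer than 1 participant per outcome group: comparisons skipped")
    return(tibble())
  }
  purrr::map_dfr(vars, function(v) {
    a <- healed[[v]][is.finite(healed[[v]])]
    b <- non[[v]][is.finite(non[[v]])]
    if (length(a) == 0 || length(b) == 0) {
      return(tibble(variable = v, n_healed = length(a), n_non_healed = length(b),
                    median_healed = NA_real_, p25_healed = NA_real_,
                    p75_healed = NA_real_, median_non_healed = NA_real_,
                    p25_non_healed = NA_real_, p75_non_healed = NA_real_,
                    p = NA_real_, r = NA_real_, effect = NA_character_))
    }
    qa <- median_iqr(a); qb <- median_iqr(b)
    mw <- mann_whitney_with_effect(a, b)
    tibble(variable = v, n_healed = length(a), n_non_healed = length(b),
           median_healed = qa$median, p25_healed = qa$p25, p75_healed = qa$p75,
           median_non_healed = qb$median, p25_non_healed = qb$p25,
           p75_non_healed = qb$p75, p = mw$p, r = mw$r, effect = mw$effect)
  })
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("CPTS cohort report:", nrow(x$measures), "participants\n\n")
  print(x$comparison)
  cat("\nCompletion by stage:\n")
  print(dplyr::filter(x$feasibility, .data$n > 0))
  invisible(x)
}

#' @rdname run_cohort
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$comparison

#' @rdname run_cohort
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n = nrow(x$measures),
    n_complete = sum(x$measures$status == "complete"),
    n_healed = sum(x$measures$healed %in% TRUE),
    median_cpts_model1 = median(x$measures$cpts_model1, na.rm = TRUE),
    median_cpts_model2 = median(x$measures$cpts_model2, na.rm = TRUE)
  )
}
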