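#' Daily cumulative plantar tissue stress, model 1
#'
#' CPTS model 1 sums, over the two conditions (in the offloading device and
#' without it), the product of the ulcer-site pressure-time integral and
#' the day's stride count in that condition:
#' \deqn{CPTS_1 = \sum_{c} (PTI_{ulcer} \times strides)_c / 1000}
#' PTI enters in kPa.s and the result is expressed in MPa.s (hence the
#' explicit division by 1000).
#'
#' @param pti_in,pti_non Ulcer-site PTI per condition (kPa.s).
#' @param strides_in,strides_non Stride counts per condition that day
#'   (vectorised over days).
#' @return Daily CPTS in MPa.s.
#' @examples
#' cpts_day_model1(66.2, 72.2, 3000, 1000)  # 270.8
#' @export
cpts_day_model1 <- function(pti_in, pti_non, strides_in, strides_non) {
  if (any(strides_in > 0 & !is.finite(pti_in)) ||
      any(strides_non > 0 & !is.finite(pti_non))) {
    abort("missing PTI for a condition with non-zero strides",
          class = "cptstress_error_missing_factor")
  }
  (ifelse(strides_in > 0, pti_in * strides_in, 0) +
     ifelse(strides_non > 0, pti_non * strides_non, 0)) / 1000
}

#' Daily cumulative plantar tissue stress, model 2
#'
#' Model 2 weights each condition's term by its thermal stress response, the
#' shear-stress surrogate:
#' \deqn{CPTS_2 = \sum_{c} (PTI_{ulcer} \times strides \times TSR)_c / 1000}
#' With TSR equal to 1 in both conditions it reduces exactly to model 1.
#' A negative TSR propagates into a possibly negative day value; callers
#' are warned once per call.
#'
#' @inheritParams cpts_day_model1
#' @param tsr_in,tsr_non Thermal stress response per condition
#'   (dimensionless).
#' @return Daily CPTS in MPa.s.
#' @export
cpts_day_model2 <- function(pti_in, pti_non, strides_in, strides_non,
                            tsr_in, tsr_non) {
  if (any(!is.finite(c(tsr_in, tsr_non)))) {
    abort("thermal stress response unavailable: model 2 cannot be computed",
          class = "cptstress_error_missing_factor")
  }
  if (any(c(tsr_in, tsr_non) < 0)) {
    warn("negative thermal stress response: model-2 day values may be negative",
         class = "cptstress_warning_negative_tsr")
  }
  (ifelse(strides_in > 0, pti_in * strides_in * tsr_in, 0) +
     ifelse(strides_non > 0, pti_non * strides_non * tsr_non, 0)) / 1000
}

#' Per-participant CPTS result
#'
#' Computes per-valid-day CPTS under model 1 and, when the thermal stress
#' response is available for both conditions, model 2, then averages over
#' valid days (the participant summary, MPa.s/day).
#'
#' @param counts Per-day condition stride counts from [classify_strides()].
#' @param pti_in,pti_non Ulcer-site PTI per condition (kPa.s).
#' @param tsr_in,tsr_non Thermal stress response per condition, or `NULL`
#'   when not measured (model 2 is then unavailable, as when no thermal
#'   camera is used).
#' @param valid_dates Dates of valid monitoring days; `NULL` uses all days
#'   in `counts`.
#' @return A `cpts_result`: list with `per_day` tibble, `summary_model1`,
#'   `summary_model2` (NA when unavailable), `n_valid_days`, and input
#'   provenance. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
cpts_result <- function(counts, pti_in, pti_non, tsr_in = NULL, tsr_non = NULL,
                        valid_dates = NULL) {
  use <- if (is.null(valid_dates)) counts else counts[counts$date %in% valid_dates, ]
  if (nrow(use) == 0) {
    abort("no valid days: CPTS summary undefined",
          class = "cptstress_error_non_adherent")
  }
  have_tsr <- !is.null(tsr_in) && !is.null(tsr_non) &&
    is.finite(tsr_in) && is.finite(tsr_non)
  per_day <- tibble(
    date = use$date,
    strides_in_device = use$strides_in_device,
    strides_non_device = use$strides_non_device,
    cpts_model1 = cpts_day_model1(pti_in, pti_non, use$strides_in_device,
                                  use$strides_non_device),
    cpts_model2 = if (have_tsr) {
      cpts_day_model2(pti_in, pti_non, use$strides_in_device,
                      use$strides_non_device, tsr_in, tsr_non)
    } else NA_real_
  )
  structure(
    list(
      per_day = per_day,
      summary_model1 = mean(per_day$cpts_model1),
      summary_model2 = if (have_tsr) mean(per_day$cpts_model2) else NA_real_,
      n_valid_days = nrow(per_day),
      inputs = list(pti_in = pti_in, pti_non = pti_non,
                    tsr_in = if (have_tsr) tsr_in else NA_real_,
                    tsr_non = if (have_tsr) tsr_non else NA_real_)
    ),
    class = "cpts_result"
  )
}

#' @export
print.cpts_result <- function(x, ...) {
  cat("Cumulative plantar tissue stress (", x$n_valid_days, " valid days)\n", sep = "")
  cat("  model 1:", format(x$summary_model1, digits = 4), "MPa.s/day\n")
  if (is.finite(x$summary_model2)) {
    cat("  model 2 (shear-weighted):", format(x$summary_model2, digits = 4),
        "MPa.s/day\n")
  } else {
    cat("  model 2: unavailable (no thermal stress response)\n")
  }
  invisible(x)
}

#' @rdname cpts_result
#' @param x A `cpts_result`.
#' @param ... Unused.
#' @method tidy cpts_result
#' @export
tidy.cpts_result <- function(x, ...) x$per_day

#' @rdname cpts_result
#' @method glance cpts_result
#' @export
glance.cpts_result <- function(x, ...) {
  tibble(
    summary_model1 = x$summary_model1,
    summary_model2 = x$summary_model2,
    n_valid_days = x$n_valid_days,
    pti_in = x$inputs$pti_in, pti_non = x$inputs$pti_non,
    tsr_in = x$inputs$tsr_in, tsr_non = x$inputs$tsr_non
  )
}

#' Average per-day CPTS values over valid days
#'
#' @param values Numeric per-day CPTS values (MPa.s).
#' @param valid Logical vector marking valid days; `NULL` keeps all.
#' @return Scalar mean over valid days (MPa.s/day).
#' @export
cpts_summary <- function(values, valid = NULL) {
  keep <- if (is.null(valid)) rep(TRUE, length(values)) else valid
  if (!any(keep)) {
    abort("no valid days: CPTS summary undefined",
          class = "cptstress_error_non_adherent")
  }
  mean(values[keep])
}
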