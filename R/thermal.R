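#' Thermal stress response
#'
#' Ratio of the index foot's relative pre-to-post-walk temperature change
#' to the contralateral foot's, evaluated on degrees Celsius exactly as the
#' quantity is defined:
#' \deqn{TSR = \frac{(post - pre)/pre \;|_{index}}{(post - pre)/pre \;|_{contra}}}
#' It serves as a surrogate for plantar shear stress. Because the
#' denominator is a Celsius ratio, the value is not invariant under adding
#' a constant to all four temperatures; this is a property of the printed
#' definition and is deliberately not "corrected". Negative values are
#' legitimate (index foot cooling while the contralateral foot warms) and
#' are passed through.
#'
#' @param pair One-row tibble `(condition, index_pre, index_post,
#'   contra_pre, contra_post)` in deg C (ROI means).
#' @return One-row tibble `(condition, tsr)`.
#' @export
thermal_stress_response <- function(pair) {
  stopifnot(nrow(pair) == 1)
  with(pair, {
    if (!all(is.finite(c(index_pre, index_post, contra_pre, contra_post)))) {
      abort("temperatures must be finite", class = "cptstress_error_input")
    }
    if (index_pre == 0 || contra_pre == 0) {
      abort("pre-walk temperatures of 0 deg C make the Celsius ratio undefined",
            class = "cptstress_error_input")
    }
    if (contra_post == contra_pre) {
      abort("undefined thermal stress response: contralateral foot unchanged",
            class = "cptstress_error_undefined_tsr")
    }
  })
  tsr <- ((pair$index_post - pair$index_pre) / pair$index_pre) /
    ((pair$contra_post - pair$contra_pre) / pair$contra_pre)
  tibble(condition = pair$condition, tsr = tsr)
}

#' Mean temperature over a region of interest
#'
#' @param readings Numeric per-pixel or per-spot temperatures (deg C).
#' @param roi Index vector selecting the region; `NULL` uses all readings.
#' @return Scalar mean temperature.
#' @export
roi_mean_temperature <- function(readings, roi = NULL) {
  vals <- if (is.null(roi)) readings else readings[roi]
  if (length(vals) == 0) abort("empty region of interest", class = "cptstress_error_input")
  mean(vals)
}
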