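# Half-open time intervals [on, off) as two-column tibbles of POSIXct.
# All sensor fusion (wear detection, stride classification, per-day clipping)
# runs on these; the half-open convention makes stride counts a partition.

new_interval_set <- function(on = as.POSIXct(character(), tz = "UTC"),
                             off = as.POSIXct(character(), tz = "UTC")) {
  stopifnot(length(on) == length(off))
  if (any(as.numeric(off) <= as.numeric(on))) {
    abort("interval `off` must be strictly after `on`", class = "cptstress_error_interval")
  }
  tibble(on = on, off = off)
}

#' Merge overlapping or touching intervals
#'
#' Collapses an interval set to disjoint ordered intervals. Intervals whose
#' gap is at most `gap_tolerance_s` seconds are merged.
#'
#' @param intervals Tibble with POSIXct columns `on`, `off`.
#' @param gap_tolerance_s Maximum gap (seconds) still merged. Default 0.
#' @return Tibble with columns `on`, `off`, disjoint and ordered.
#' @export
merge_intervals <- function(intervals, gap_tolerance_s = 0) {
  if (nrow(intervals) == 0) return(intervals)
  x <- dplyr::arrange(intervals, .data$on)
  on <- as.numeric(x$on); off <- as.numeric(x$off)
  keep_on <- on[1]; keep_off <- off[1]
  res_on <- c(); res_off <- c()
  for (i in seq_along(on)[-1]) {
    if (on[i] <= keep_off + gap_tolerance_s) {
      keep_off <- max(keep_off, off[i])
    } else {
      res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
  tibble(
    on = as.POSIXct(res_on, origin = "1970-01-01", tz = "UTC"),
    off = as.POSIXct(res_off, origin = "1970-01-01", tz = "UTC")
  )
}

# TRUE for each time point falling in some [on, off)
in_intervals <- function(times, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(times)))
  t <- as.numeric(times)
  on <- as.numeric(intervals$on); off <- as.numeric(intervals$off)
  # findInterval against the sorted boundary sequence; odd slot = inside
  bounds <- as.vector(rbind(on, off))
  stopifnot(!is.unsorted(bounds))
  findInterval(t, bounds, left.open = FALSE) %% 2L == 1L
}

# Intersect an interval set with a single [start, end) window
clip_intervals <- function(intervals, start, end) {
  if (nrow(intervals) == 0) return(intervals)
  out <- intervals |>
    dplyr::mutate(on = pmax(.data$on, start), off = pmin(.data$off, end)) |>
    dplyr::filter(.data$off > .data$on)
  out
}

# Complement of an interval set within [start, end)
complement_intervals <- function(intervals, start, end) {
  iv <- clip_intervals(merge_intervals(intervals), start, end)
  if (nrow(iv) == 0) return(new_interval_set(start, end))
  edges_on <- c(start, iv$off)
  edges_off <- c(iv$on, end)
  keep <- as.numeric(edges_off) > as.numeric(edges_on)
  tibble(on = edges_on[keep], off = edges_off[keep])
}

interval_hours <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(as.numeric(intervals$off) - as.numeric(intervals$on)) / 3600
}

# Shrink every interval by `margin_s` at both ends, dropping emptied ones
inset_intervals <- function(intervals, margin_s) {
  if (nrow(intervals) == 0) return(intervals)
  intervals |>
    dplyr::mutate(on = .data$on + margin_s, off = .data$off - margin_s) |>
    dplyr::filter(.data$off > .data$on)
}

utc_day <- function(times) as.Date(format(times, tz = "UTC"))
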