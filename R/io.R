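# CSV/JSON stream dialects. Timestamps are ISO-8601 UTC with millisecond
# precision; pressure series carry a .geom.json sidecar with the sensor
# geometry so a frame file is self-describing.

iso_fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

parse_iso <- function(x, path = "<memory>") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  t <- as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    abort(sprintf("%s: malformed timestamp at data row %d: '%s'", path, bad, x[bad]),
          class = "cptstress_error_format")
  }
  t
}

geom_path <- function(path) sub("\\.csv$", ".geom.json", path)

#' Write a pressure frame series to CSV (plus geometry sidecar)
#'
#' @param series A `pressure_frames` series.
#' @param path Output CSV path; the geometry goes to the `.geom.json`
#'   sidecar next to it.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(series, path) {
  readr::write_csv(as_tibble(series), path, progress = FALSE)
  jsonlite::write_json(
    list(
      dialect = pf_attr(series, "dialect"),
      sampling_rate = pf_attr(series, "sampling_rate"),
      sensors = pf_attr(series, "geometry")
    ),
    geom_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write stride events / temperature log / intervals / thermal pairs
#'
#' Small writers for the remaining stream dialects: stride events
#' (`timestamp_iso`), temperature logs (`timestamp_iso`, `temp_c`),
#' interval sets (`on_iso`, `off_iso`) and thermal reading pairs (JSON).
#'
#' @param x The object to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name stream-writers
NULL

#' @rdname stream-writers
#' @export
write_strides_csv <- function(x, path) {
  readr::write_csv(tibble(timestamp_iso = iso_fmt(x$time)), path, progress = FALSE)
  invisible(path)
}

#' @rdname stream-writers
#' @export
write_acceleration_csv <- function(x, path) {
  readr::write_csv(tibble(time_s = as.numeric(x$time), ax_g = x$ax_g,
                          ay_g = x$ay_g, az_g = x$az_g),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname stream-writers
#' @export
write_temperature_csv <- function(x, path) {
  readr::write_csv(tibble(timestamp_iso = iso_fmt(x$time), temp_c = x$temp_c),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname stream-writers
#' @export
write_intervals_csv <- function(x, path) {
  readr::write_csv(tibble(on_iso = iso_fmt(x$on), off_iso = iso_fmt(x$off)),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname stream-writers
#' @export
write_thermal_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_csv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cptstress_error_io")
  }
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE,
                                         progress = FALSE))
  if (nrow(df) == 0) {
    abort(paste0(path, ": empty stream file"), class = "cptstress_error_input")
  }
  pb <- readr::problems(df)
  if (nrow(pb) > 0) {
    abort(sprintf("%s: %d malformed row(s), first at row %d: %s",
                  path, nrow(pb), pb$row[1], pb$expected[1]),
          class = "cptstress_error_format")
  }
  if (!all(expected_cols %in% names(df))) {
    abort(sprintf("%s: expected columns %s, found %s", path,
                  paste(expected_cols, collapse = ", "),
                  paste(names(df), collapse = ", ")),
          class = "cptstress_error_format")
  }
  df
}

#' Read a typed sensor stream
#'
#' Dispatches on `kind` and returns the validated typed object the
#' downstream modules consume. Malformed files raise a format error naming
#' the file and row; temperature logs with gaps longer than 2 h are parsed
#' with gap metadata in the `gaps` attribute.
#'
#' @param path File path.
#' @param kind One of `"pressure"`, `"acceleration"`, `"temperature"`,
#'   `"thermal"`, `"strides"`, `"intervals"`.
#' @return The typed series (see the corresponding module).
#' @export
read_stream <- function(path, kind = c("pressure", "acceleration", "temperature",
                                       "thermal", "strides", "intervals")) {
  kind <- match.arg(kind)
  switch(
    kind,
    pressure = {
      df <- read_csv_checked(path, "time_s")
      gp <- geom_path(path)
      if (!file.exists(gp)) {
        abort(paste0(path, ": missing geometry sidecar ", gp),
              class = "cptstress_error_format")
      }
      meta <- jsonlite::read_json(gp, simplifyVector = TRUE)
      pressure_frames(df, dialect = meta$dialect,
                      sampling_rate = meta$sampling_rate,
                      geometry = as_tibble(meta$sensors))
    },
    acceleration = {
      df <- read_csv_checked(path, c("time_s", "ax_g", "ay_g", "az_g"))
      out <- tibble(time = as.POSIXct(df$time_s, origin = "1970-01-01", tz = "UTC"),
                    ax_g = df$ax_g, ay_g = df$ay_g, az_g = df$az_g)
      attr(out, "sampling_rate") <- 1 / median(diff(df$time_s))
      out
    },
    temperature = {
      df <- read_csv_checked(path, c("timestamp_iso", "temp_c"))
      out <- tibble(time = parse_iso(df$timestamp_iso, path), temp_c = df$temp_c)
      gaps <- which(diff(as.numeric(out$time)) > 2 * 3600)
      attr(out, "gaps") <- tibble(after = out$time[gaps],
                                  gap_h = diff(as.numeric(out$time))[gaps] / 3600)
      out
    },
    thermal = {
      if (!file.exists(path)) abort(paste0("file not found: ", path),
                                    class = "cptstress_error_io")
      as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
    },
    strides = {
      df <- read_csv_checked(path, "timestamp_iso")
      out <- tibble(time = parse_iso(df$timestamp_iso, path))
      attr(out, "source") <- "file"
      out
    },
    intervals = {
      df <- read_csv_checked(path, c("on_iso", "off_iso"))
      new_interval_set(parse_iso(df$on_iso, path), parse_iso(df$off_iso, path))
    }
  )
}
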