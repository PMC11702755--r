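#' Construct a validated tri-axial accelerometer recording
#'
#' An `accel_recording` is a tibble with columns `time` (seconds, strictly
#' increasing) and `x`, `y`, `z` (acceleration per axis in consistent,
#' arbitrary units), carrying the sampling rate and the identity of the
#' dorso-ventral axis as attributes. All downstream spectral math is
#' unit-covariant (per-window normalization removes the scale), so no
#' particular physical unit is assumed.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y,z Acceleration per axis; equal lengths.
#' @param sample_rate Nominal sampling rate in Hz (the study's sensors run at
#'   200 Hz). The median inter-sample interval must agree with
#'   `1/sample_rate` within 1%.
#' @param dv_axis Which channel is the dorso-ventral axis: `"x"`, `"y"` or
#'   `"z"`.
#' @param animal_id Optional identifier carried through summaries.
#'
#' @return A tibble of class `accel_recording`.
#' @export
accel_recording <- function(time, x, y, z, sample_rate, dv_axis = "z",
                            animal_id = NA_character_) {
  n <- length(time)
  if (length(x) != n || length(y) != n || length(z) != n) {
    abort_format("Acceleration channels must all have the length of `time`.")
  }
  if (n < 2L) abort_format("A recording needs at least two samples.")
  dt <- diff(time)
  bad <- which(dt <= 0)
  if (length(bad)) {
    abort_format(sprintf(
      "Timestamps must be strictly increasing; first violation at row %d.",
      bad[1] + 1L))
  }
  stopifnot_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  if (abs(median(dt) - 1 / sample_rate) > 0.01 / sample_rate) {
    abort_format(sprintf(
      "Median inter-sample interval %.6g s is not within 1%% of 1/sample_rate = %.6g s.",
      median(dt), 1 / sample_rate))
  }
  if (!dv_axis %in% c("x", "y", "z")) {
    abort_format("`dv_axis` must name an existing channel: 'x', 'y' or 'z'.")
  }
  gaps <- which(dt > 5 * median(dt))
  if (length(gaps)) {
    warn(sprintf("%d gap(s) longer than 5 median intervals (first after row %d).",
                 length(gaps), gaps[1]))
  }
  out <- tibble(time = as.numeric(time), x = as.numeric(x),
                y = as.numeric(y), z = as.numeric(z))
  structure(out,
            sample_rate = sample_rate, dv_axis = dv_axis, animal_id = animal_id,
            class = c("accel_recording", class(out)))
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz, dv_axis = %s, animal = %s\n",
              nrow(x), attr(x, "sample_rate"), attr(x, "dv_axis"),
              attr(x, "animal_id")))
  NextMethod()
}

#' Read a tri-axial accelerometer CSV
#'
#' Expects a timestamp column plus three acceleration columns (a WEAR/Harp
#' style export re-serialized to CSV). Column names are declarable so that
#' differently-labelled exports can be ingested without editing files.
#'
#' @param path CSV file path.
#' @param dv_axis Dorso-ventral axis after renaming: `"x"`, `"y"` or `"z"`.
#' @param sample_rate Nominal rate in Hz; if `NULL`, inferred as
#'   `1/median(diff(time))`.
#' @param col_time,col_x,col_y,col_z Source column names.
#' @param animal_id Optional identifier.
#'
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, dv_axis = "z", sample_rate = NULL,
                           col_time = "time", col_x = "ax", col_y = "ay",
                           col_z = "az", animal_id = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(col_time, col_x, col_y, col_z)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("Missing column(s) in %s: %s.",
                         path, paste(missing_cols, collapse = ", ")))
  }
  tm <- df[[col_time]]
  if (is.null(sample_rate)) sample_rate <- 1 / median(diff(tm))
  accel_recording(tm, df[[col_x]], df[[col_y]], df[[col_z]],
                  sample_rate = sample_rate, dv_axis = dv_axis,
                  animal_id = animal_id)
}

#' Write an accelerometer recording to CSV
#'
#' Values round-trip through [read_accel_csv()] exactly (readr serializes
#' doubles with shortest round-trip precision).
#'
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  df <- tibble(time = rec$time, ax = rec$x, ay = rec$y, az = rec$z)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
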