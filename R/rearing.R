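#' Rearing detection parameters
#'
#' The cylinder-test readout: the animal rears when the height of its
#' mounted sensor exceeds a per-setup threshold, and an epoch counts as one
#' rearing event if sustained for at least 0.5 s (inclusive, unlike the
#' strict immobility rule). Thresholds are setup-specific and must be
#' supplied explicitly (in the study they were read off calibration
#' trajectory plots).
#'
#' @param height_threshold Height threshold in the trace's units (px).
#' @param min_duration_s Minimum sustained duration in seconds.
#' @return A list of class `rearing_params`.
#' @export
rearing_params <- function(height_threshold = 160, min_duration_s = 0.5) {
  if (min_duration_s <= 0) abort_param("`min_duration_s` must be > 0.")
  structure(list(height_threshold = height_threshold,
                 min_duration_s = min_duration_s),
            class = c("rearing_params", "list"))
}

#' Detect rearing events in a sensor-height trace
#'
#' Maximal runs with height above `height_threshold` sustained for at least
#' `min_duration_s` each count as one rearing event.
#'
#' @param heights Tibble with `time` (s) and `height` columns (e.g. from
#'   [simulate_height_trace()], or the sensor bodypart of a cylinder
#'   [pose_track()] converted to height).
#' @param params A [rearing_params()].
#' @return A list with `count` and `events` (tibble `start`, `end`,
#'   `duration` in seconds).
#' @export
detect_rearing <- function(heights, params = rearing_params()) {
  h <- heights$height
  t <- heights$time
  if (params$height_threshold < min(h) || params$height_threshold > max(h)) {
    warn("Height threshold lies outside the observed height range.",
         class = "motorpheno_config_warning")
  }
  fr <- 1 / median(diff(t))
  runs <- runs_of(h > params$height_threshold)
  up <- runs[runs$value, , drop = FALSE]
  dur <- (up$end_idx - up$start_idx + 1L) / fr
  keep <- dur >= params$min_duration_s - 1e-9
  events <- tibble(start = t[up$start_idx[keep]] - 1 / fr,
                   end = t[up$end_idx[keep]],
                   duration = dur[keep])
  list(count = nrow(events), events = events)
}

#' Sensor height from a cylinder pose track
#'
#' Converts the image y coordinate of the sensor bodypart (pixels from the
#' top of the side-view frame) into a height trace, optionally excluding
#' low-likelihood frames.
#'
#' @param track A cylinder-arena [pose_track()].
#' @param bodypart Sensor bodypart name.
#' @param image_height_px Image height used to flip the y axis.
#' @param likelihood_min Frames below this likelihood are dropped.
#' @return Tibble with `time` and `height` (px from the frame bottom).
#' @export
sensor_height <- function(track, bodypart = "sensor", image_height_px = 1024,
                          likelihood_min = 0.95) {
  sub <- track |>
    filter(.data$bodypart == !!bodypart,
           .data$likelihood >= likelihood_min) |>
    arrange(.data$frame)
  if (!nrow(sub)) abort_input(sprintf("No retained frames for bodypart '%s'.", bodypart))
  tibble(time = sub$time, height = image_height_px - sub$y)
}
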