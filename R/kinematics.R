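#' Kinematics parameters
#'
#' Defaults follow the study's open-field analysis: likelihood cutoff 0.95
#' (estimates below it are excluded outright, never interpolated), 5-frame
#' median filter, immobility at < 0.5 cm/s sustained strictly longer than
#' 0.5 s, analysis restricted to the 5-20 minute mark of a 30-minute
#' session, and the spine2 centroid.
#'
#' @param likelihood_min Exclusion threshold on tracking likelihood.
#' @param median_filter_len Median filter length in frames (odd).
#' @param speed_threshold Immobility speed threshold, cm/s.
#' @param min_bout_s Minimum immobility duration in seconds (strict: a bout
#'   must last *more* than this).
#' @param analysis_window `c(start, end)` in seconds, or `NULL` for the full
#'   recording.
#' @param bodypart Centroid bodypart.
#' @return A list of class `kinematics_params`.
#' @export
kinematics_params <- function(likelihood_min = 0.95, median_filter_len = 5,
                              speed_threshold = 0.5, min_bout_s = 0.5,
                              analysis_window = c(300, 1200),
                              bodypart = "spine2") {
  if (median_filter_len %% 2 != 1) abort_param("`median_filter_len` must be odd.")
  if (speed_threshold <= 0 || min_bout_s <= 0) {
    abort_param("Thresholds must be > 0.")
  }
  structure(list(likelihood_min = likelihood_min,
                 median_filter_len = median_filter_len,
                 speed_threshold = speed_threshold, min_bout_s = min_bout_s,
                 analysis_window = analysis_window, bodypart = bodypart),
            class = c("kinematics_params", "list"))
}

#' Filter a pose track
#'
#' Marks frames with likelihood below the cutoff as excluded (they carry no
#' coordinates into any metric) and median-filters the coordinates of each
#' bodypart over its valid frames.
#'
#' @param track A [pose_track()].
#' @param params A [kinematics_params()].
#' @return The track with an added logical `excluded` column and filtered
#'   `x`, `y`.
#' @export
filter_pose <- function(track, params = kinematics_params()) {
  k <- params$median_filter_len
  out <- track |>
    mutate(excluded = .data$likelihood < params$likelihood_min) |>
    group_by(.data$bodypart) |>
    mutate(x = smooth_valid(.data$x, .data$excluded, k),
           y = smooth_valid(.data$y, .data$excluded, k)) |>
    ungroup()
  if (all(out$excluded)) {
    warn_empty("Every frame falls below the likelihood cutoff.")
  }
  attributes(out)[c("frame_rate", "px_per_cm", "arena", "animal_id")] <-
    attributes(track)[c("frame_rate", "px_per_cm", "arena", "animal_id")]
  class(out) <- class(track)
  out
}

# Running median over the subsequence of valid frames; excluded frames keep
# their raw value but are never consumed by downstream metrics.
smooth_valid <- function(v, excluded, k) {
  idx <- which(!excluded)
  if (length(idx) >= k) {
    v[idx] <- as.numeric(runmed(v[idx], k, endrule = "median"))
  }
  v
}

#' Per-frame centroid speed
#'
#' Speed at frame t is the Euclidean displacement of the centroid bodypart
#' from frame t-1 to t, times the frame rate, divided by the pixel
#' calibration (backward difference). The first frame, and any frame whose
#' backward pair includes an excluded frame, carries no speed (`NA`).
#'
#' @param track A filtered [pose_track()] (see [filter_pose()]).
#' @param params A [kinematics_params()].
#' @return A tibble of class `speed_series` with `frame`, `time`, `speed`
#'   (cm/s) and `excluded`.
#' @export
compute_speed <- function(track, params = kinematics_params()) {
  px_per_cm <- attr(track, "px_per_cm")
  fr <- attr(track, "frame_rate")
  if (is.null(px_per_cm) || !is.numeric(px_per_cm)) {
    abort_config("`px_per_cm` calibration is required to compute speed.")
  }
  sub <- track |>
    filter(.data$bodypart == params$bodypart) |>
    arrange(.data$frame)
  if (!nrow(sub)) {
    abort_config(sprintf("Bodypart '%s' not present in the track.", params$bodypart))
  }
  if (!"excluded" %in% names(sub)) sub$excluded <- FALSE
  disp <- sqrt((sub$x - lag(sub$x))^2 + (sub$y - lag(sub$y))^2)
  speed <- disp * fr / px_per_cm
  speed[sub$excluded | lag(sub$excluded, default = TRUE)] <- NA_real_
  out <- tibble(frame = sub$frame, time = sub$time, speed = speed,
                excluded = sub$excluded)
  structure(out, frame_rate = fr, animal_id = attr(track, "animal_id"),
            class = c("speed_series", class(out)))
}

clip_window <- function(speed, window) {
  if (is.null(window)) return(speed)
  t0 <- speed$time[1]; t1 <- speed$time[nrow(speed)]
  fr <- attr(speed, "frame_rate")
  if (window[1] < t0 - 1.5 / fr || window[2] > t1 + 0.5 / fr) {
    abort_param(sprintf(
      "Analysis window [%g, %g] s is not contained in the recording [%g, %g] s.",
      window[1], window[2], t0, t1))
  }
  out <- filter(speed, .data$time > window[1], .data$time <= window[2] + 1e-9)
  attributes(out)[c("frame_rate", "animal_id")] <-
    attributes(speed)[c("frame_rate", "animal_id")]
  class(out) <- class(speed)
  out
}

#' Segment a speed series into mobility bouts
#'
#' Maximal runs with speed below `speed_threshold` lasting strictly more
#' than `min_bout_s` are labelled `immobile`; shorter sub-threshold runs are
#' absorbed into the surrounding `mobile` state. Frames without a valid
#' speed (likelihood exclusions and the first frame) break runs and are
#' labelled `excluded`. Each frame's speed covers the inter-frame interval
#' ending at its timestamp, so a run of frames at times `t1..t2` yields the
#' half-open interval `[t1 - 1/frame_rate, t2)`.
#'
#' @param speed A [compute_speed()] result (optionally windowed).
#' @param params A [kinematics_params()]; `analysis_window` is applied when
#'   not `NULL` and the series extends beyond it.
#' @return A tibble of class `bout_segmentation` with `start`, `end`,
#'   `state` tiling the analysis window.
#' @export
segment_bouts <- function(speed, params = kinematics_params()) {
  fr <- attr(speed, "frame_rate")
  speed <- clip_window(speed, params$analysis_window)
  cls <- ifelse(is.na(speed$speed), "excluded",
                ifelse(speed$speed < params$speed_threshold, "sub", "super"))
  runs <- runs_of(cls)
  runs$n <- runs$end_idx - runs$start_idx + 1L
  runs$state <- ifelse(
    runs$value == "excluded", "excluded",
    ifelse(runs$value == "sub" & runs$n / fr > params$min_bout_s,
           "immobile", "mobile"))
  # merge adjacent intervals of equal state (absorbed sub runs join mobile)
  merged <- runs_of(runs$state)
  out <- tibble(
    start = speed$time[runs$start_idx[merged$start_idx]] - 1 / fr,
    end = speed$time[runs$end_idx[merged$end_idx]],
    state = merged$value
  )
  structure(out, frame_rate = fr, animal_id = attr(speed, "animal_id"),
            window = c(out$start[1], out$end[nrow(out)]),
            class = c("bout_segmentation", class(out)))
}

frame_states <- function(seg, times) {
  idx <- findInterval(times - 1e-9, seg$start)
  ifelse(idx >= 1 & times <= seg$end[pmax(idx, 1)] + 1e-9,
         seg$state[pmax(idx, 1)], NA_character_)
}

#' Locomotion metrics from a bout segmentation
#'
#' Immobility time (the akinesia readout), mean speed during mobility only
#' (the bradykinesia readout), the number of stops (immobile bouts), and
#' total distance travelled over valid frames.
#'
#' @param seg A [segment_bouts()] result.
#' @param speed The same [compute_speed()] series the segmentation was
#'   computed from.
#' @param params A [kinematics_params()].
#' @return A one-row tibble of class `locomotion_metrics`.
#' @export
locomotion_metrics <- function(seg, speed, params = kinematics_params()) {
  fr <- attr(seg, "frame_rate")
  speed <- clip_window(speed, params$analysis_window)
  st <- frame_states(seg, speed$time)
  immobile <- filter(seg, .data$state == "immobile")
  mobile_speeds <- speed$speed[!is.na(st) & st == "mobile" & !is.na(speed$speed)]
  if (!length(mobile_speeds)) {
    warn_empty("No mobile frames: mean mobile speed is undefined.")
    mms <- NA_real_
  } else {
    mms <- mean(mobile_speeds)
  }
  tibble(
    animal_id = attr(seg, "animal_id") %||% NA_character_,
    immobility_time = sum(immobile$end - immobile$start),
    mobile_mean_speed = mms,
    n_stops = nrow(immobile),
    total_distance = sum(speed$speed, na.rm = TRUE) / fr
  ) |>
    structure(class = c("locomotion_metrics", class(tibble())))
}

#' Stop and move duration densities
#'
#' Kernel density estimates (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of immobile-bout ("stop") and mobile-bout ("move") durations,
#' renormalized to integrate to 1 on the reported grid. With a single
#' interval of a state the density is degenerate; a histogram fallback is
#' returned with a warning.
#'
#' @param seg A [segment_bouts()] result.
#' @param n_grid Grid resolution per state.
#' @return A tibble of class `duration_density` with `state` (`stop` /
#'   `move`), `duration` (s) and `density`.
#' @export
duration_distributions <- function(seg, n_grid = 512) {
  states <- list(stop = "immobile", move = "mobile")
  out <- map_dfr(names(states), function(nm) {
    d <- seg$end[seg$state == states[[nm]]] - seg$start[seg$state == states[[nm]]]
    if (!length(d)) {
      abort_input(sprintf("No %s interval present in the segmentation.", nm))
    }
    if (length(d) == 1L || sd(d) == 0) {
      # a point mass has no kernel bandwidth; fall back to a narrow histogram
      if (length(d) == 1L) {
        warn(sprintf("Single %s interval: density is degenerate, returning a histogram.", nm),
             class = "motorpheno_degenerate_density")
      }
      half <- max(d[1] * 0.05, 0.05)
      return(tibble(state = nm, duration = d[1], density = 1 / (2 * half)))
    }
    de <- density(d, bw = "nrd0", n = n_grid)
    dens <- de$y / trapz(de$x, de$y)
    tibble(state = nm, duration = de$x, density = dens)
  })
  structure(out, class = c("duration_density", class(out)))
}
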