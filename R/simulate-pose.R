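#' Parameters for the synthetic open-field trajectory generator
#'
#' Behavior is modeled as a two-state semi-Markov process alternating mobile
#' and immobile bouts with log-normal dwell times (so the segmenter's strict
#' 0.5 s minimum-duration rule can be probed near its boundary). Within
#' mobile bouts the per-frame speed is log-normal around a cruising speed
#' well above the 0.5 cm/s immobility threshold; immobile frames carry only
#' small positional jitter. Likelihood dropout emulates tracking failures:
#' dropped frames get a likelihood below the 0.95 cutoff.
#'
#' @param duration Seconds of video (study sessions: 30 min at 30 Hz).
#' @param frame_rate Hz.
#' @param mobile_dwell,immobile_dwell Log-normal dwell parameters
#'   `c(meanlog, sdlog)` in log-seconds.
#' @param mobile_speed Log-normal per-frame speed parameters
#'   `c(meanlog, sdlog)` in log-cm/s.
#' @param immobile_speed_sd Immobile-frame speed scale in cm/s (0 gives a
#'   perfectly still animal).
#' @param dropout Per-frame probability of a low-likelihood estimate, in
#'   `[0, 1)`.
#' @param arena_cm Side length of the square arena (study: 40 cm).
#' @param px_per_cm Pixel calibration of the synthetic "camera". The default
#'   puts the 40 cm arena across a 1280 px image width.
#' @param seed Generator seed.
#' @return A list of class `bout_sim_params`.
#' @export
bout_sim_params <- function(duration = 1800, frame_rate = 30,
                            mobile_dwell = c(meanlog = log(6), sdlog = 0.6),
                            immobile_dwell = c(meanlog = log(2), sdlog = 0.8),
                            mobile_speed = c(meanlog = log(8), sdlog = 0.25),
                            immobile_speed_sd = 0.1,
                            dropout = 0.01,
                            arena_cm = 40, px_per_cm = 1280 / 40,
                            seed = 1L) {
  p <- list(duration = duration, frame_rate = frame_rate,
            mobile_dwell = mobile_dwell, immobile_dwell = immobile_dwell,
            mobile_speed = mobile_speed, immobile_speed_sd = immobile_speed_sd,
            dropout = dropout, arena_cm = arena_cm, px_per_cm = px_per_cm,
            seed = as.integer(seed))
  if (exp(p$mobile_dwell[1]) <= 0 || exp(p$immobile_dwell[1]) <= 0) {
    abort_param("Dwell means must be > 0.")
  }
  if (p$dropout < 0 || p$dropout >= 1) abort_param("`dropout` must lie in [0, 1).")
  if (p$immobile_speed_sd < 0) abort_param("`immobile_speed_sd` must be >= 0.")
  structure(p, class = c("bout_sim_params", "list"))
}

#' Simulate a bout-structured pose track
#'
#' Draws alternating mobile/immobile dwells, integrates per-frame
#' displacements with a persistent random heading, reflects the trajectory
#' at the arena walls and emits a single-bodypart (`spine2`) track.
#' `truth$intervals` records the frame-quantized state intervals (the state
#' governing each frame's displacement), so a segmenter run on noise-free
#' output can be compared against them exactly.
#'
#' @param params A [bout_sim_params()].
#' @param arena `"open_field"` (the only supported arena for trajectories).
#' @param animal_id Identifier.
#' @return A list with `track` (a [pose_track()]) and `truth` (state per
#'   frame, state intervals in seconds, per-frame true speeds, parameters).
#' @export
simulate_pose <- function(params = bout_sim_params(), arena = "open_field",
                          animal_id = "sim") {
  if (!identical(arena, "open_field")) {
    abort_param("Trajectory simulation supports arena = 'open_field' only.")
  }
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration * p$frame_rate)
    # draw dwell sequence until it covers the session
    state <- character(0); covered <- 0; states_t <- numeric(0)
    cur <- sample(c("mobile", "immobile"), 1)
    while (covered < p$duration) {
      dw <- if (cur == "mobile") {
        rlnorm(1, p$mobile_dwell[1], p$mobile_dwell[2])
      } else {
        rlnorm(1, p$immobile_dwell[1], p$immobile_dwell[2])
      }
      state <- c(state, cur); states_t <- c(states_t, dw)
      covered <- covered + dw
      cur <- if (cur == "mobile") "immobile" else "mobile"
    }
    bounds <- cumsum(c(0, states_t))
    # state at each frame's timestamp (frame i covers [i-1, i)/rate; speed of
    # frame i is the displacement over that interval)
    frame_time <- seq_len(n) / p$frame_rate
    frame_state <- state[findInterval(frame_time - 0.5 / p$frame_rate, bounds,
                                      rightmost.closed = TRUE)]
    mob <- frame_state == "mobile"
    speed <- numeric(n)
    speed[mob] <- rlnorm(sum(mob), p$mobile_speed[1], p$mobile_speed[2])
    if (p$immobile_speed_sd > 0) {
      speed[!mob] <- abs(rnorm(sum(!mob), 0, p$immobile_speed_sd))
    }
    # persistent heading: wrapped Gaussian increments, faster turning when slow
    heading <- cumsum(rnorm(n, 0, 0.4))
    step <- speed / p$frame_rate
    pos <- matrix(0, n + 1, 2)
    pos[1, ] <- runif(2, 0.25, 0.75) * p$arena_cm
    dxy <- cbind(step * cos(heading), step * sin(heading))
    raw <- rbind(pos[1, , drop = FALSE],
                 matrix(pos[1, ], n, 2, byrow = TRUE) + apply(dxy, 2, cumsum))
    # reflect at the walls by folding the unbounded path into [0, arena]
    fold <- function(u, L) {
      v <- u %% (2 * L)
      ifelse(v > L, 2 * L - v, v)
    }
    xy <- cbind(fold(raw[, 1], p$arena_cm), fold(raw[, 2], p$arena_cm))
    # frame k (0-based) sits at time k / frame_rate; its backward-difference
    # speed covers ((k-1), k] / frame_rate, governed by frame_state[k]
    drop_frame <- runif(n + 1) < p$dropout
    likelihood <- ifelse(drop_frame, runif(n + 1, 0.2, 0.949), runif(n + 1, 0.96, 1))
    df <- tibble(frame = 0:n,
                 bodypart = "spine2",
                 x = xy[, 1] * p$px_per_cm,
                 y = xy[, 2] * p$px_per_cm,
                 likelihood = likelihood)
    track <- pose_track(df, frame_rate = p$frame_rate, px_per_cm = p$px_per_cm,
                        arena = "open_field", animal_id = animal_id)
    runs <- runs_of(frame_state)
    intervals <- tibble(
      start = (runs$start_idx - 1L) / p$frame_rate,
      end = runs$end_idx / p$frame_rate,
      state = runs$value
    )
    truth <- list(params = p, frame_state = frame_state, speed = speed,
                  intervals = intervals, dropout = drop_frame,
                  animal_id = animal_id)
    list(track = track, truth = truth)
  })
}

#' Simulate a cylinder-test sensor-height trace
#'
#' Baseline sensor height with plateaus above threshold during planted
#' rearing events, mirroring the side-view cylinder assay in which rearing
#' is read from the height of the animal-mounted sensor.
#'
#' @param events Data frame with columns `start` and `duration` (seconds);
#'   events must not overlap.
#' @param duration Trace length in seconds (default covers the last event).
#' @param frame_rate Hz.
#' @param noise_sd Height noise in px.
#' @param baseline,event_height Height levels in px.
#' @param seed Generator seed.
#' @return A list with `heights` (tibble `time`, `height`) and `truth`
#'   (event table, count, threshold midway between levels).
#' @export
simulate_height_trace <- function(events, duration = NULL, frame_rate = 30,
                                  noise_sd = 0, baseline = 100,
                                  event_height = 220, seed = 1L) {
  events <- as_tibble(events)
  if (nrow(events)) {
    ord <- order(events$start)
    ev <- events[ord, ]
    if (any(ev$duration <= 0)) abort_param("Event durations must be > 0.")
    if (nrow(ev) > 1 &&
        any(head(ev$start + ev$duration, -1) > tail(ev$start, -1))) {
      abort_param("Rearing events must not overlap.")
    }
  } else {
    ev <- events
  }
  if (is.null(duration)) {
    duration <- if (nrow(ev)) max(ev$start + ev$duration) + 2 else 10
  }
  with_seed(seed, {
    n <- round(duration * frame_rate)
    t <- seq_len(n) / frame_rate
    h <- rep(baseline, n)
    for (i in seq_len(nrow(ev))) {
      sel <- t > ev$start[i] & t <= ev$start[i] + ev$duration[i]
      h[sel] <- event_height
    }
    if (noise_sd > 0) h <- h + rnorm(n, 0, noise_sd)
    truth <- list(events = ev, count = nrow(ev),
                  threshold = (baseline + event_height) / 2,
                  frame_rate = frame_rate)
    list(heights = tibble(time = t, height = h), truth = truth)
  })
}
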