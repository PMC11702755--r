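#' Parameters for the synthetic accelerometer generator
#'
#' The generator emulates a body-mounted tri-axial sensor on a freely moving
#' mouse: a static gravity component projected on the three axes, broadband
#' measurement noise, short locomotion bursts on all axes, and a narrow-band
#' tremor oscillation injected on the dorso-ventral axis whose amplitude
#' follows an age schedule. The default tremor frequency, 15.625 Hz, sits
#' exactly on a 256-sample spectrogram bin at 200 Hz (bin 20) and inside the
#' 12-18 Hz band where the pathological oscillation emerges, so spectral
#' oracles are analytic.
#'
#' @param duration Recording length in seconds.
#' @param sample_rate Hz (study sensors: 200).
#' @param gravity_mag Gravity magnitude in the recording's (arbitrary,
#'   consistent) acceleration units.
#' @param gravity_orientation Unit 3-vector giving the sensor attitude.
#' @param tremor_freq Tremor frequency in Hz; must be below Nyquist.
#' @param tremor_amp Age schedule: list with numeric `age_weeks` and `amp`
#'   (amplitudes >= 0, same units as the noise). Ages between knots are
#'   linearly interpolated, outside they are clamped.
#' @param noise_sd Broadband noise standard deviation per axis (marginal sd).
#' @param noise_ar First-lag autocorrelation of the noise, in `[0, 1)`.
#'   Body micro-motion and sensor drift weight the acceleration spectrum
#'   toward low frequencies; an AR(1) process reproduces that 1/f-like
#'   shape (0 gives white noise).
#' @param burst_rate Locomotion transient rate in events/s.
#' @param burst_amp Peak scale of locomotion transients.
#' @param dv_axis Axis carrying the tremor.
#' @param seed Generator seed.
#' @return A list of class `tremor_sim_params`.
#' @export
tremor_sim_params <- function(duration = 300, sample_rate = 200,
                              gravity_mag = 1,
                              gravity_orientation = c(0, 0, 1),
                              tremor_freq = 15.625,
                              tremor_amp = list(age_weeks = c(8, 16, 24),
                                                amp = c(0, 0.5, 1)),
                              noise_sd = 0.1, noise_ar = 0.9,
                              burst_rate = 0.2, burst_amp = 0.5,
                              dv_axis = "z", seed = 1L) {
  p <- list(duration = duration, sample_rate = sample_rate,
            gravity_mag = gravity_mag,
            gravity_orientation = gravity_orientation / sqrt(sum(gravity_orientation^2)),
            tremor_freq = tremor_freq, tremor_amp = tremor_amp,
            noise_sd = noise_sd, noise_ar = noise_ar, burst_rate = burst_rate,
            burst_amp = burst_amp, dv_axis = dv_axis, seed = as.integer(seed))
  if (any(p$tremor_amp$amp < 0)) abort_param("Tremor amplitudes must be >= 0.")
  if (p$tremor_freq >= p$sample_rate / 2) {
    abort_param("`tremor_freq` must be below Nyquist (sample_rate / 2).")
  }
  if (p$noise_sd < 0 || p$burst_amp < 0 || p$burst_rate < 0) {
    abort_param("Noise and burst parameters must be >= 0.")
  }
  if (p$noise_ar < 0 || p$noise_ar >= 1) abort_param("`noise_ar` must lie in [0, 1).")
  structure(p, class = c("tremor_sim_params", "list"))
}

tremor_amp_at <- function(schedule, age_weeks) {
  if (length(schedule$age_weeks) == 1L) return(schedule$amp)
  approx(schedule$age_weeks, schedule$amp, xout = age_weeks, rule = 2)$y
}

#' Simulate an accelerometer recording with an injected tremor
#'
#' @param params A [tremor_sim_params()].
#' @param age_weeks Animal age; sets the tremor amplitude via the schedule.
#' @param animal_id Identifier attached to the recording.
#' @return A list with elements `recording` (an [accel_recording()]) and
#'   `truth` (generator parameters plus the realized tremor amplitude, phase
#'   and locomotion burst times).
#' @export
simulate_accel <- function(params = tremor_sim_params(), age_weeks = 24,
                           animal_id = "sim") {
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration * p$sample_rate)
    t <- seq_len(n) / p$sample_rate
    g <- p$gravity_mag * p$gravity_orientation
    acc <- matrix(rep(g, each = n), ncol = 3)
    if (p$noise_sd > 0) {
      innov_sd <- p$noise_sd * sqrt(1 - p$noise_ar^2)
      for (ax in 1:3) {
        e <- rnorm(n, sd = innov_sd)
        acc[, ax] <- acc[, ax] + if (p$noise_ar > 0) {
          as.numeric(stats::filter(e, p$noise_ar, method = "recursive"))
        } else e
      }
    }
    # locomotion transients: Gaussian-windowed low-frequency wiggles on all axes
    n_bursts <- rpois(1, p$burst_rate * p$duration)
    burst_times <- sort(runif(n_bursts, 0, p$duration))
    for (bt in burst_times) {
      width <- runif(1, 0.15, 0.4)
      freq <- runif(1, 2, 8)
      phase <- runif(3, 0, 2 * pi)
      amp <- p$burst_amp * runif(3, 0.3, 1)
      env <- exp(-((t - bt)^2) / (2 * width^2))
      for (ax in 1:3) {
        acc[, ax] <- acc[, ax] + amp[ax] * env * sin(2 * pi * freq * t + phase[ax])
      }
    }
    amp_t <- tremor_amp_at(p$tremor_amp, age_weeks)
    phase_t <- runif(1, 0, 2 * pi)
    dv <- match(p$dv_axis, c("x", "y", "z"))
    acc[, dv] <- acc[, dv] + amp_t * sin(2 * pi * p$tremor_freq * t + phase_t)
    rec <- accel_recording(t, acc[, 1], acc[, 2], acc[, 3],
                           sample_rate = p$sample_rate, dv_axis = p$dv_axis,
                           animal_id = animal_id)
    truth <- list(params = p, age_weeks = age_weeks,
                  tremor_amp = amp_t, tremor_phase = phase_t,
                  burst_times = burst_times, animal_id = animal_id)
    list(recording = rec, truth = truth)
  })
}
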