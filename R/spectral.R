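#' Spectral analysis parameters
#'
#' Defaults follow the study's tremor pipeline: 5th-order 1 Hz low-pass
#' Butterworth gravity separation, 256-sample spectrogram segments with 50%
#' overlap, a Tukey(0.25) taper, per-window 0-1 normalization and the
#' 12-18 Hz tremor band. `gate_overlap_min` is the minimum fraction of a
#' window's span that must fall inside immobile intervals for the window to
#' be retained when gating: windows (1.28 s at 200 Hz) are longer than the
#' minimum immobility bout (0.5 s), so requiring full containment would
#' discard valid tremor epochs.
#'
#' @param filter_order Butterworth order.
#' @param filter_cutoff Low-pass cutoff in Hz.
#' @param window_len Segment length in samples.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param band Tremor band `c(lo, hi)` in Hz, inclusive on the bin grid.
#' @param gate_overlap_min Minimum window/interval overlap fraction, in
#'   `(0, 1]`.
#' @param window_shape Tukey taper shape parameter in `[0, 1]` (0 =
#'   rectangular, 1 = Hann).
#' @param detrend Per-segment detrending: `"constant"` removes each
#'   segment's mean, `"none"` leaves it.
#' @param band_stat `"mean_bins_median_windows"` (per-window mean over band
#'   bins, then median over windows) or `"median_cells"` (median over all
#'   band bin-by-window cells).
#' @param use_raw_axis If `TRUE`, the spectrogram input is the raw
#'   dorso-ventral axis rather than the gravity-subtracted one.
#' @return A list of class `spectral_params`.
#' @export
spectral_params <- function(filter_order = 5, filter_cutoff = 1,
                            window_len = 256, overlap = 0.5,
                            band = c(12, 18), gate_overlap_min = 0.75,
                            window_shape = 0.25,
                            detrend = c("constant", "none"),
                            band_stat = c("mean_bins_median_windows",
                                          "median_cells"),
                            use_raw_axis = FALSE) {
  detrend <- match.arg(detrend)
  band_stat <- match.arg(band_stat)
  if (overlap < 0 || overlap >= 1) abort_param("`overlap` must lie in [0, 1).")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort_param("`band` must be c(lo, hi) with 0 < lo < hi.")
  }
  if (gate_overlap_min <= 0 || gate_overlap_min > 1) {
    abort_param("`gate_overlap_min` must lie in (0, 1].")
  }
  structure(list(filter_order = filter_order, filter_cutoff = filter_cutoff,
                 window_len = window_len, overlap = overlap, band = band,
                 gate_overlap_min = gate_overlap_min,
                 window_shape = window_shape, detrend = detrend,
                 band_stat = band_stat, use_raw_axis = use_raw_axis),
            class = c("spectral_params", "list"))
}

#' Estimate the gravitational acceleration component
#'
#' Applies the low-pass Butterworth filter to each axis in zero-phase
#' (forward-backward) form, so the gravity estimate is not delayed relative
#' to the raw series before subtraction; the effective attenuation is the
#' squared magnitude response. The first and last 2 s are flagged as edge
#' region in the `edge` column.
#'
#' @param rec An [accel_recording()].
#' @param params A [spectral_params()].
#' @return Tibble with `time`, low-frequency `x`, `y`, `z`, and logical
#'   `edge`.
#' @export
estimate_gravity <- function(rec, params = spectral_params()) {
  fs <- attr(rec, "sample_rate")
  n <- nrow(rec)
  tc <- 1 / (2 * pi * params$filter_cutoff)
  if (n / fs <= 10 * tc) {
    abort_processing(sprintf(
      "Recording (%.3g s) must be longer than 10 filter time constants (%.3g s).",
      n / fs, 10 * tc))
  }
  sos <- butter_lowpass_sos(params$filter_order, params$filter_cutoff, fs)
  edge_s <- max(2, 3 / params$filter_cutoff)
  out <- tibble(
    time = rec$time,
    x = sos_filtfilt(sos, rec$x),
    y = sos_filtfilt(sos, rec$y),
    z = sos_filtfilt(sos, rec$z),
    edge = rec$time < rec$time[1] + edge_s | rec$time > rec$time[n] - edge_s
  )
  structure(out, sample_rate = fs, dv_axis = attr(rec, "dv_axis"),
            class = class(out))
}

#' Body acceleration: raw minus gravitational component
#'
#' @param rec An [accel_recording()].
#' @param gravity Output of [estimate_gravity()] on the same recording.
#' @return Tibble with `time` and per-axis body acceleration `x`, `y`, `z`.
#' @export
body_acceleration <- function(rec, gravity = estimate_gravity(rec)) {
  if (nrow(rec) != nrow(gravity)) {
    abort_processing("Recording and gravity estimate differ in length.")
  }
  out <- tibble(time = rec$time,
                x = rec$x - gravity$x,
                y = rec$y - gravity$y,
                z = rec$z - gravity$z)
  structure(out, sample_rate = attr(rec, "sample_rate"),
            dv_axis = attr(rec, "dv_axis"), class = class(out))
}

#' Total body acceleration (vector norm)
#'
#' @param body Per-axis body acceleration (tibble with `x`, `y`, `z`).
#' @return Tibble with `time` and `tba`, the per-sample Euclidean norm.
#' @export
total_body_acceleration <- function(body) {
  if (!all(c("x", "y", "z") %in% names(body))) {
    abort_processing("Three axes (x, y, z) are required.")
  }
  tibble(time = body$time, tba = sqrt(body$x^2 + body$y^2 + body$z^2))
}

tukey_window <- function(n, shape) {
  if (shape <= 0) return(rep(1, n))
  if (shape >= 1) return(0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))))
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- t < shape / 2
  hi <- t > 1 - shape / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / shape - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / shape - 2 / shape + 1)))
  w
}

#' Short-time Fourier spectrogram
#'
#' Consecutive windowed Fourier power estimates over segments of
#' `window_len` samples hopping by `window_len * (1 - overlap)`; the
#' one-sided frequency grid is `f_k = k * sample_rate / window_len`. Power
#' is scaled so that with a rectangular window, no overlap and no
#' detrending the bins of one segment sum to that segment's mean square
#' (Parseval).
#'
#' @param x Numeric series (the dorso-ventral body-acceleration axis in the
#'   tremor pipeline).
#' @param sample_rate Hz.
#' @param params A [spectral_params()].
#' @return A list of class `spectrogram`: `freqs` (Hz), `times` (window
#'   centers, s), `power` (freq x window matrix), `normalized`,
#'   `sample_rate`, `window_len`, `hop`.
#' @export
compute_spectrogram <- function(x, sample_rate, params = spectral_params()) {
  nw <- params$window_len
  n <- length(x)
  if (n < nw) {
    abort_processing(sprintf("Series (%d samples) shorter than one window (%d).",
                             n, nw))
  }
  hop <- round(nw * (1 - params$overlap))
  n_win <- floor((n - nw) / hop) + 1L
  w <- tukey_window(nw, params$window_shape)
  scale <- nw * sum(w^2)
  n_freq <- nw %/% 2 + 1L
  pow <- matrix(0, n_freq, n_win)
  starts <- (seq_len(n_win) - 1L) * hop
  for (j in seq_len(n_win)) {
    seg <- x[starts[j] + seq_len(nw)]
    if (params$detrend == "constant") seg <- seg - mean(seg)
    X <- fft(w * seg)[seq_len(n_freq)]
    p <- Mod(X)^2 / scale
    # one-sided doubling of interior bins (DC and Nyquist appear once)
    p[2:(n_freq - 1L)] <- 2 * p[2:(n_freq - 1L)]
    pow[, j] <- p
  }
  structure(list(
    freqs = (seq_len(n_freq) - 1L) * sample_rate / nw,
    times = (starts + nw / 2) / sample_rate,
    power = pow,
    normalized = FALSE,
    sample_rate = sample_rate, window_len = nw, hop = hop
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins x %d windows (%s), fs = %g Hz\n",
              length(x$freqs), length(x$times),
              if (x$normalized) "normalized" else "raw power", x$sample_rate))
  invisible(x)
}

#' Normalize a spectrogram window-wise to the 0-1 range
#'
#' Each window column is mapped to `(p - min) / (max - min)`; a constant
#' column becomes all zeros (absence of spectral structure should not
#' masquerade as full band power). Idempotent.
#'
#' @param spec A [compute_spectrogram()] result.
#' @return The spectrogram with `normalized = TRUE`.
#' @export
normalize_spectrogram <- function(spec) {
  p <- spec$power
  mins <- apply(p, 2, min)
  maxs <- apply(p, 2, max)
  rng <- maxs - mins
  for (j in seq_len(ncol(p))) {
    p[, j] <- if (rng[j] > 0) (p[, j] - mins[j]) / rng[j] else 0
  }
  spec$power <- p
  spec$normalized <- TRUE
  spec
}

band_bin_index <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

#' Band-power summary of a normalized spectrogram
#'
#' The per-window band value is the mean normalized power over the band
#' bins (inclusive at both band edges on the analytic grid
#' `f_k = k * fs / window_len`); the animal-level summary is the median of
#' the per-window values over retained windows. When immobile intervals are
#' supplied, only windows overlapping them by at least `gate_overlap_min`
#' of their span are retained, quantifying the tremor present while the
#' animal is immobile.
#'
#' @param spec A normalized [compute_spectrogram()] result.
#' @param params A [spectral_params()]; supplies the band, the gate
#'   threshold and the band statistic.
#' @param gate_intervals Optional tibble of immobile intervals with columns
#'   `start`, `end` in seconds.
#' @param animal_id Identifier carried into the summary row.
#' @return A one-row tibble of class `spectral_summary`: `animal_id`,
#'   `band_power`, `n_windows_used`, `gated`, with the per-window series in
#'   attribute `per_window`. If gating retains no window, `band_power` is
#'   `NA` and an empty-result warning is signalled.
#' @export
band_power_summary <- function(spec, params = spectral_params(),
                               gate_intervals = NULL, animal_id = NA_character_) {
  if (!spec$normalized) {
    abort_processing("Band power is defined on the normalized spectrogram; call normalize_spectrogram() first.")
  }
  bins <- band_bin_index(spec, params$band)
  if (!length(bins)) abort_param("No spectrogram bin falls inside `band`.")
  per_window <- if (params$band_stat == "mean_bins_median_windows") {
    colMeans(spec$power[bins, , drop = FALSE])
  } else {
    apply(spec$power[bins, , drop = FALSE], 2, median)
  }
  keep <- rep(TRUE, length(per_window))
  gated <- !is.null(gate_intervals)
  if (gated) {
    half <- spec$window_len / 2 / spec$sample_rate
    w_start <- spec$times - half
    w_end <- spec$times + half
    ov <- vapply(seq_along(spec$times), function(j) {
      sum(pmax(0, pmin(w_end[j], gate_intervals$end) -
                   pmax(w_start[j], gate_intervals$start)))
    }, numeric(1))
    keep <- ov / (2 * half) >= params$gate_overlap_min
  }
  if (!any(keep)) {
    warn_empty("No spectrogram window retained after immobility gating.")
    summary_val <- NA_real_
  } else if (params$band_stat == "median_cells") {
    summary_val <- median(spec$power[bins, keep, drop = FALSE])
  } else {
    summary_val <- median(per_window[keep])
  }
  out <- tibble(animal_id = animal_id, band_power = summary_val,
                n_windows_used = sum(keep), n_windows = length(per_window),
                gated = gated)
  structure(out, per_window = tibble(time = spec$times, band_power = per_window,
                                     retained = keep),
            class = c("spectral_summary", class(out)))
}

#' Tremor band power of a recording (full pipeline)
#'
#' Convenience wrapper chaining gravity separation, body acceleration,
#' spectrogram of the dorso-ventral axis, 0-1 normalization and the band
#' summary.
#'
#' @param rec An [accel_recording()].
#' @param params A [spectral_params()].
#' @param gate_intervals Optional immobile intervals (`start`, `end` in s).
#' @return A [band_power_summary()] row.
#' @export
tremor_band_power <- function(rec, params = spectral_params(),
                              gate_intervals = NULL) {
  dv <- attr(rec, "dv_axis")
  series <- if (params$use_raw_axis) {
    rec[[dv]]
  } else {
    # gravity separation of the dv channel only (the other axes do not enter
    # the spectrogram); identical to the full body_acceleration() result
    sos <- butter_lowpass_sos(params$filter_order, params$filter_cutoff,
                              attr(rec, "sample_rate"))
    rec[[dv]] - sos_filtfilt(sos, rec[[dv]])
  }
  spec <- compute_spectrogram(series, attr(rec, "sample_rate"), params) |>
    normalize_spectrogram()
  band_power_summary(spec, params, gate_intervals = gate_intervals,
                     animal_id = attr(rec, "animal_id"))
}

#' Export a spectrogram as a dense CSV matrix
#'
#' Writes the power matrix with a `freq_hz` first column and one column per
#' window labelled by its center time in seconds; [read_spectrogram_csv()]
#' restores the object.
#'
#' @param spec A [compute_spectrogram()] result (normalized or raw).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path) {
  df <- as_tibble(as.data.frame(spec$power))
  names(df) <- sprintf("t_%.6f", spec$times)
  df <- dplyr::bind_cols(tibble(freq_hz = spec$freqs), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_spectrogram_csv
#' @param sample_rate,window_len,normalized Metadata not stored in the CSV.
#' @export
read_spectrogram_csv <- function(path, sample_rate, window_len,
                                 normalized = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  times <- as.numeric(sub("^t_", "", names(df)[-1]))
  structure(list(freqs = df$freq_hz, times = times,
                 power = unname(as.matrix(df[, -1])), normalized = normalized,
                 sample_rate = sample_rate, window_len = window_len,
                 hop = if (length(times) > 1) round(diff(times[1:2]) * sample_rate) else NA_integer_),
            class = "spectrogram")
}
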