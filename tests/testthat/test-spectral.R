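fs <- 200

test_that("gravity filter passes DC and slow tilt, rejects tremor-band content", {
  n <- 4000
  rec <- accel_recording(seq_len(n) / fs, rep(0, n), rep(0, n), rep(9.81, n),
                         sample_rate = fs)
  grav <- estimate_gravity(rec)
  expect_lt(max(abs(grav$z - 9.81)), 1e-9)
  expect_lt(max(abs(grav$x)), 1e-9)

  # 15 Hz unit sinusoid: analytic squared-magnitude response of the
  # zero-phase 5th-order filter at 15x cutoff is ~1.4e-12, so the leaked
  # amplitude must be < 1e-4
  t <- seq_len(20 * fs) / fs
  rec2 <- accel_recording(t, sin(2 * pi * 15 * t), rep(0, length(t)),
                          rep(1, length(t)), sample_rate = fs)
  g2 <- estimate_gravity(rec2)
  expect_lt(max(abs(g2$x[!g2$edge])), 1e-4)

  # 0.05 Hz tilt passes with amplitude ratio > 0.99
  t3 <- seq_len(100 * fs) / fs
  rec3 <- accel_recording(t3, sin(2 * pi * 0.05 * t3), rep(0, length(t3)),
                          rep(1, length(t3)), sample_rate = fs)
  g3 <- estimate_gravity(rec3)
  expect_gt(max(abs(g3$x)) / 1, 0.99)

  # analytic magnitude response agrees with the filtered attenuation
  sos <- motorpheno:::butter_lowpass_sos(5, 1, fs)
  expect_lt(motorpheno:::sos_filtfilt_gain(sos, 15), 1e-8)
  expect_equal(motorpheno:::sos_filtfilt_gain(sos, 0), 1, tolerance = 1e-12)

  expect_error(estimate_gravity(accel_recording(seq_len(200) / fs,
                                                rep(0, 200), rep(0, 200),
                                                rep(1, 200), sample_rate = fs)),
               class = "motorpheno_processing_error")
})

test_that("body acceleration is the exact residual and is linear", {
  n <- 6000
  t <- seq_len(n) / fs
  rec <- accel_recording(t, rnorm(n), rnorm(n), 1 + rnorm(n), sample_rate = fs)
  grav <- estimate_gravity(rec)
  body <- body_acceleration(rec, grav)
  expect_equal(body$x, rec$x - grav$x)
  # rec equal to its own gravity estimate gives zeros
  rec_g <- accel_recording(t, grav$x, grav$y, grav$z, sample_rate = fs)
  body0 <- body_acceleration(rec_g, estimate_gravity(rec_g))
  # a >= 10 Hz additive component is recovered almost exactly
  s <- sin(2 * pi * 12 * t)
  rec_s <- accel_recording(t, rec$x + s, rec$y, rec$z, sample_rate = fs)
  g_s <- estimate_gravity(rec_s)
  body_s <- body_acceleration(rec_s, g_s)
  mid <- !g_s$edge
  expect_lt(sqrt(mean((body_s$x[mid] - (body$x[mid] + s[mid]))^2)) /
              sqrt(mean(s[mid]^2)), 1e-3)
  # linearity of the filter: joint filtering equals the sum of parts
  a <- rnorm(n); b <- rnorm(n)
  sos <- motorpheno:::butter_lowpass_sos(5, 1, fs)
  lhs <- motorpheno:::sos_filtfilt(sos, a + b)
  rhs <- motorpheno:::sos_filtfilt(sos, a) + motorpheno:::sos_filtfilt(sos, b)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(body_acceleration(rec, grav[1:10, ]),
               class = "motorpheno_processing_error")
})

test_that("total body acceleration is the per-sample Euclidean norm", {
  body <- tibble::tibble(time = 1:3, x = c(3, 0, 1), y = c(4, 0, 2), z = c(0, 0, 2))
  expect_equal(total_body_acceleration(body)$tba, c(5, 0, 3))
  # invariant to axis permutation
  perm <- tibble::tibble(time = 1:3, x = body$z, y = body$x, z = body$y)
  expect_equal(total_body_acceleration(perm)$tba,
               total_body_acceleration(body)$tba)
})

test_that("spectrogram geometry, peak location and Parseval hold", {
  # window count from the definition: floor((2000 - 256) / 128) + 1 = 14
  x <- rnorm(2000)
  spec <- compute_spectrogram(x, fs, spectral_params())
  expect_equal(length(spec$times), 14)
  expect_equal(spec$freqs, (0:128) * fs / 256)

  # a 15.625 Hz sinusoid (exactly bin 20) peaks at that bin in every window
  t <- seq_len(4000) / fs
  s <- sin(2 * pi * 15.625 * t)
  sp <- compute_spectrogram(s, fs, spectral_params())
  peak_freq <- sp$freqs[apply(sp$power, 2, which.max)]
  expect_true(all(peak_freq == 15.625))

  # Parseval: rectangular window, no overlap, no detrend
  pars <- spectral_params(window_shape = 0, overlap = 0, detrend = "none")
  y <- rnorm(1024)
  sp2 <- compute_spectrogram(y, fs, pars)
  for (j in seq_along(sp2$times)) {
    seg <- y[(j - 1) * 256 + 1:256]
    expect_equal(sum(sp2$power[, j]), mean(seg^2), tolerance = 1e-6)
  }

  expect_error(compute_spectrogram(rnorm(100), fs, spectral_params()),
               class = "motorpheno_processing_error")
})

test_that("spectrogram matches the direct-DFT oracle", {
  x <- rnorm(768)
  spec <- compute_spectrogram(x, fs, spectral_params())
  orc <- oracle_spectrogram(x, fs)
  expect_equal(spec$freqs, orc$freqs)
  expect_lt(max(abs(spec$power - orc$power)) / max(orc$power), 1e-10)
})

test_that("normalization maps windows to [0,1], is idempotent, rank-preserving", {
  x <- rnorm(2000)
  sp <- compute_spectrogram(x, fs, spectral_params())
  np <- normalize_spectrogram(sp)
  expect_true(all(apply(np$power, 2, max) == 1))
  expect_true(all(apply(np$power, 2, min) == 0))
  expect_equal(normalize_spectrogram(np)$power, np$power)
  for (j in seq_len(ncol(sp$power))) {
    expect_equal(order(np$power[, j]), order(sp$power[, j]))
  }
  # constant columns become all-zero
  sp$power[, 1] <- 5
  expect_true(all(normalize_spectrogram(sp)$power[, 1] == 0))
})

test_that("band bins and band-power summary follow the inclusive-grid rule", {
  x <- rnorm(2000)
  np <- normalize_spectrogram(compute_spectrogram(x, fs, spectral_params()))
  # fs 200 / window 256: band bins are k = 16..23 (12.5 .. 17.96875 Hz)
  bins <- motorpheno:::band_bin_index(np, c(12, 18))
  expect_equal(bins, 17:24)  # 1-based indices of k = 16..23
  expect_equal(np$freqs[bins], (16:23) * fs / 256)

  # extremal case: band bins all 1, everything else below 1
  np2 <- np
  np2$power[] <- 0.3
  np2$power[bins, ] <- 1
  np2$power[1, ] <- 0  # keep each column's min at 0
  s <- band_power_summary(np2, spectral_params())
  expect_equal(s$band_power, 1)

  # gating: full-cover intervals match the ungated summary
  s_all <- band_power_summary(np, spectral_params())
  s_gate <- band_power_summary(np, spectral_params(),
                               gate_intervals = tibble::tibble(start = 0, end = 10))
  expect_equal(s_gate$band_power, s_all$band_power)
  expect_true(s_gate$gated && !s_all$gated)

  # gating that retains nothing yields an explicit empty result
  expect_warning(
    s0 <- band_power_summary(np, spectral_params(),
                             gate_intervals = tibble::tibble(start = 100, end = 101)),
    class = "motorpheno_empty_result")
  expect_true(is.na(s0$band_power))
  expect_equal(s0$n_windows_used, 0)
})

test_that("band power rises with tremor amplitude across seeds", {
  bp <- function(amp, seed) {
    p <- tremor_sim_params(duration = 30, seed = seed, noise_sd = 1,
                           tremor_amp = list(age_weeks = 24, amp = amp))
    tremor_band_power(simulate_accel(p, 24)$recording)$band_power
  }
  ords <- vapply(1:20, function(s) {
    v <- c(bp(0, s), bp(0.5, s + 1000), bp(1, s + 2000))
    v[1] < v[2] && v[2] < v[3]
  }, logical(1))
  expect_gte(mean(ords), 0.95)
})

test_that("tremor trend recovers a noiseless line and respects invariances", {
  ages <- c(8, 8, 16, 16, 24, 24)
  df <- tibble::tibble(age_weeks = ages, band_power = 0.006 * ages + 0.036)
  tr <- tremor_trend(df)
  expect_equal(tr$pearson_r, 1)
  expect_equal(tr$slope, 0.006)
  expect_equal(tr$intercept, 0.036)
  expect_equal(tr$r_squared, 1)
  # translation of ages leaves r and slope unchanged
  df2 <- dplyr::mutate(df, age_weeks = age_weeks + 100)
  tr2 <- tremor_trend(df2)
  expect_equal(tr2$pearson_r, tr$pearson_r)
  expect_equal(tr2$slope, tr$slope)
  expect_error(tremor_trend(df[1:2, ]), class = "motorpheno_input_error")
  df3 <- dplyr::mutate(df, band_power = 0.1)
  expect_error(tremor_trend(df3), class = "motorpheno_degenerate_error")
  # glance returns the full fit row
  g <- glance(tr)
  expect_named(g, c("pearson_r", "p_value", "slope", "intercept",
                    "r_squared", "n"))
})

test_that("permuted band powers give a uniform p-value null", {
  set.seed(808)
  n <- 24
  ages <- rep(c(8, 16, 24), each = 8)
  bp <- rnorm(n, 0.1, 0.02)
  ps <- vapply(1:1000, function(i) {
    tremor_trend(tibble::tibble(age_weeks = ages,
                                band_power = sample(bp)))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("spectrogram CSV export round-trips the normalized matrix", {
  tmp <- withr::local_tempdir()
  np <- normalize_spectrogram(compute_spectrogram(rnorm(1024), fs, spectral_params()))
  path <- file.path(tmp, "spec.csv")
  write_spectrogram_csv(np, path)
  back <- read_spectrogram_csv(path, sample_rate = fs, window_len = 256)
  expect_equal(back$freqs, np$freqs)
  expect_equal(back$times, np$times, tolerance = 1e-6)
  expect_equal(back$power, np$power, tolerance = 1e-12)
})
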