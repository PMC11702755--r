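# Independent oracles and small fixture builders used across test files.

# Direct-DFT spectrogram oracle: per-window power computed from first
# principles, independent of compute_spectrogram()'s vectorization.
oracle_spectrogram <- function(x, sample_rate, window_len = 256, overlap = 0.5,
                               shape = 0.25, detrend = "constant") {
  hop <- round(window_len * (1 - overlap))
  n_win <- floor((length(x) - window_len) / hop) + 1
  # Tukey taper built from its piecewise definition
  tt <- (seq_len(window_len) - 1) / (window_len - 1)
  w <- ifelse(tt < shape / 2, 0.5 * (1 + cos(pi * (2 * tt / shape - 1))),
         ifelse(tt > 1 - shape / 2,
                0.5 * (1 + cos(pi * (2 * tt / shape - 2 / shape + 1))), 1))
  n_freq <- window_len %/% 2 + 1
  k <- 0:(window_len %/% 2)
  pow <- matrix(0, n_freq, n_win)
  for (j in seq_len(n_win)) {
    seg <- x[(j - 1) * hop + seq_len(window_len)]
    if (detrend == "constant") seg <- seg - mean(seg)
    seg <- seg * w
    for (ki in seq_along(k)) {
      ang <- -2 * pi * k[ki] * (seq_len(window_len) - 1) / window_len
      re <- sum(seg * cos(ang)); im <- sum(seg * sin(ang))
      pow[ki, j] <- (re^2 + im^2) / (window_len * sum(w^2))
    }
  }
  pow[2:(n_freq - 1), ] <- 2 * pow[2:(n_freq - 1), ]
  list(freqs = k * sample_rate / window_len, power = pow)
}

# Brute-force bout segmentation oracle: explicit per-frame loop over the
# run-length rules (sub-threshold runs strictly longer than min_bout_s are
# immobile; NA speeds break runs and are excluded).
oracle_segment <- function(speed, frame_rate, thr = 0.5, min_s = 0.5) {
  cls <- ifelse(is.na(speed), "excluded",
                ifelse(speed < thr, "sub", "super"))
  n <- length(cls)
  state <- character(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && cls[j + 1] == cls[i]) j <- j + 1
    lab <- if (cls[i] == "excluded") "excluded"
           else if (cls[i] == "sub" && (j - i + 1) / frame_rate > min_s) "immobile"
           else "mobile"
    state[i:j] <- lab
    i <- j + 1
  }
  state
}

# Exact Mann-Whitney two-sided p by exhaustive enumeration of all
# choose(n1+n2, n1) assignments of ranks (tie-free samples only).
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

make_cell_table <- function(counts_case, counts_control, n_case = 100,
                            n_control = 100) {
  # two mice, one cluster of interest "A" against the rest "B"
  tibble::tibble(
    cell_id = sprintf("c%d", seq_len(n_case + n_control)),
    mouse_id = rep(c("m_case", "m_ctrl"), c(n_case, n_control)),
    genotype = rep(c("case", "control"), c(n_case, n_control)),
    sex = "F", age_group = 16, batch = "b1",
    cluster = c(rep(c("A", "B"), c(counts_case, n_case - counts_case)),
                rep(c("A", "B"), c(counts_control, n_control - counts_control)))
  ) |> motorpheno::cell_table()
}
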