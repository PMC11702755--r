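# Zero-phase Butterworth low-pass filtering in second-order-sections form.
#
# The gravity-separation filter sits at 1 Hz on a 200 Hz stream, i.e. a
# normalized cutoff of 0.01: at that ratio the expanded order-5 transfer
# function (b, a) is numerically ill-conditioned (direct-form filtering of a
# constant leaves O(1e-7) errors), so the design is kept as cascaded biquads.
# Each biquad is obtained by bilinear transform of one conjugate pole pair of
# the Butterworth analog prototype and normalized to unit DC gain.

butter_lowpass_sos <- function(order, cutoff, sample_rate) {
  stopifnot_scalar_number(order, "order", positive = TRUE)
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= sample_rate / 2) abort_param("`cutoff` must be below Nyquist.")
  wc <- 2 * sample_rate * tan(pi * cutoff / sample_rate)  # pre-warped analog cutoff
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left half-plane poles
  zp <- (2 * sample_rate + p) / (2 * sample_rate - p)          # bilinear transform
  sos <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {           # real pole (odd order)
      a <- c(1, -Re(zp[i])); b <- c(1, 1)
    } else {
      j <- which(!used & seq_len(order) != i & abs(zp - Conj(zp[i])) < 1e-9)[1]
      used[j] <- TRUE
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2); b <- c(1, 2, 1)
    }
    used[i] <- TRUE
    b <- b * (sum(a) / sum(b))              # unit gain at DC per section
    sos[[length(sos) + 1L]] <- list(b = b, a = a)
  }
  structure(list(sections = sos, order = order, cutoff = cutoff,
                 sample_rate = sample_rate),
            class = "butter_sos")
}

# One causal pass through the cascade, each section initialized at the
# steady state for a constant input equal to the first sample.
sos_filter_steady <- function(sos, x) {
  for (s in sos$sections) {
    x <- signal::filter(s$b, s$a, x,
                        init.x = rep(x[1], length(s$b) - 1L),
                        init.y = rep(x[1], length(s$a) - 1L))
  }
  as.numeric(x)
}

# Forward-backward (zero-phase) application with symmetric-extension padding
# long enough (10 filter time constants) to absorb start-up transients;
# effective attenuation is the squared magnitude response. Symmetric (even)
# mirroring is used rather than odd reflection: over a long pad an odd
# extension shifts the padded segment's mean by 2*x[1], which a low-pass
# passes straight into the data, whereas the even extension is DC-neutral
# (its kink only adds attenuated high-frequency content).
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  padlen <- min(ceiling(10 * sos$sample_rate / sos$cutoff), n - 1L)
  if (padlen < 1L) abort_processing("Series too short to filter.")
  ext <- c(x[(padlen + 1):2], x, x[(n - 1):(n - padlen)])
  y <- sos_filter_steady(sos, ext)
  y <- rev(sos_filter_steady(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# Squared magnitude response of the zero-phase filter at frequency f (Hz).
sos_filtfilt_gain <- function(sos, f) {
  z <- exp(2i * pi * f / sos$sample_rate)
  h <- rep(1 + 0i, length(f))
  for (s in sos$sections) {
    h <- h * (s$b[1] + s$b[2] / z + (if (length(s$b) > 2) s$b[3] / z^2 else 0)) /
      (s$a[1] + s$a[2] / z + (if (length(s$a) > 2) s$a[3] / z^2 else 0))
  }
  Mod(h)^2
}
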