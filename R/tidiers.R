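#' Tidy a spectrogram into a long tibble
#'
#' @param x A [compute_spectrogram()] result.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `power`.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble(time = rep(x$times, each = length(x$freqs)),
         freq = rep(x$freqs, length(x$times)),
         power = as.vector(x$power))
}

#' @rdname tidy.spectrogram
#' @export
glance.spectrogram <- function(x, ...) {
  tibble(n_freqs = length(x$freqs), n_windows = length(x$times),
         sample_rate = x$sample_rate, window_len = x$window_len,
         hop = x$hop, normalized = x$normalized)
}

#' Tidy an abundance result
#'
#' @param x An `abundance_result` (see [differential_abundance()]).
#' @param ... Unused.
#' @return The per-cluster table as a plain tibble (forest-plot ready).
#' @export
tidy.abundance_result <- function(x, ...) {
  as_tibble(x)[, c("cluster", "log_or", "ci_low", "ci_high",
                   "p_value", "fdr_q", "significant")]
}

#' @rdname tidy.abundance_result
#' @export
glance.abundance_result <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_fitted = sum(x$converged),
         n_significant = sum(x$significant, na.rm = TRUE),
         fdr_alpha = attr(x, "params")$fdr_alpha)
}
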