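# ggplot2 front-ends for the main result types.

#' Plot a spectrogram
#'
#' @param object A [compute_spectrogram()] result (normalize first for the
#'   0-1 display used in the tremor figures).
#' @param max_freq Upper frequency limit of the display, Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram <- function(object, max_freq = 30, ...) {
  df <- tidy(object) |> filter(.data$freq <= max_freq)
  ggplot(df, aes(.data$time, .data$freq, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (object$normalized) "norm. power" else "power") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Forest plot of per-cluster log odds ratios
#'
#' @param object An `abundance_result` (see [differential_abundance()]).
#' @param ... Unused.
#' @return A ggplot mirroring the odds-ratio dot-and-whisker panels.
#' @export
autoplot.abundance_result <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$log_or))
  ggplot(df, aes(.data$log_or, stats::reorder(.data$cluster, .data$log_or),
                 color = .data$significant)) +
    geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point() +
    labs(x = "log odds ratio (case vs control)", y = NULL, color = "FDR sig.") +
    theme_minimal()
}

#' Plot stop/move duration densities
#'
#' @param object A [duration_distributions()] result.
#' @param ... Unused.
#' @return A ggplot with one panel per state.
#' @export
autoplot.duration_density <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$duration, .data$density)) +
    geom_line() +
    facet_wrap(~state, scales = "free") +
    labs(x = "duration (s)", y = "probability density") +
    theme_minimal()
}

#' Plot an open-field trajectory colored by mobility state
#'
#' @param track A [pose_track()].
#' @param seg Optional [segment_bouts()] result used to color the path.
#' @param params A [kinematics_params()] (for the bodypart).
#' @return A ggplot.
#' @export
plot_trajectory <- function(track, seg = NULL, params = kinematics_params()) {
  sub <- filter(track, .data$bodypart == params$bodypart)
  if ("excluded" %in% names(sub)) sub <- filter(sub, !.data$excluded)
  if (!is.null(seg)) sub$state <- frame_states(seg, sub$time)
  p <- ggplot(sub, aes(.data$x, .data$y))
  p <- if (is.null(seg)) p + geom_path(linewidth = 0.2) else
    p + geom_path(aes(color = .data$state), linewidth = 0.2)
  p + labs(x = "x (px)", y = "y (px)") + theme_minimal()
}
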