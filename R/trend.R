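#' Age trend of tremor band power
#'
#' Pearson correlation between per-animal band power and age (two-sided p
#' from the t distribution with n - 2 df) together with the ordinary
#' least-squares line, as used to quantify the progressive intensification
#' of the 12-18 Hz oscillation.
#'
#' @param summaries Data frame with one row per animal containing the band
#'   power and age columns.
#' @param band_power,age Column names.
#' @return An object of class `trend_fit` with fields `pearson_r`,
#'   `p_value`, `slope`, `intercept`, `r_squared`, `n`. [tidy()] and
#'   [glance()] methods are provided.
#' @export
tremor_trend <- function(summaries, band_power = "band_power", age = "age_weeks") {
  y <- summaries[[band_power]]
  x <- summaries[[age]]
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort_input("Trend estimation needs at least 3 animals.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort(sprintf("Correlation undefined: %s has zero variance.",
                  if (sd(x) == 0) age else band_power),
          class = "motorpheno_degenerate_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- lm(y ~ x)
  structure(list(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n = n,
    fit = fit
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> n = %d: r = %.3f (p = %.3g), y = %.3gx + %.3g, R^2 = %.3f\n",
    x$n, x$pearson_r, x$p_value, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @rdname tremor_trend
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tremor_trend
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, p_value = x$p_value, slope = x$slope,
         intercept = x$intercept, r_squared = x$r_squared, n = x$n)
}
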