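# Internal helpers shared across modules.

# Run `code` with a reproducible RNG state and restore the caller's state.
# The generator kind is pinned (Mersenne-Twister / Inversion / Rejection) so
# simulated datasets are identical across platforms and R sessions regardless
# of the session's RNGkind.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

abort_format <- function(msg, ...) abort(msg, class = "motorpheno_format_error", ...)
abort_param <- function(msg, ...) abort(msg, class = "motorpheno_parameter_error", ...)
abort_processing <- function(msg, ...) abort(msg, class = "motorpheno_processing_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "motorpheno_config_error", ...)
abort_input <- function(msg, ...) abort(msg, class = "motorpheno_input_error", ...)
abort_design <- function(msg, ...) abort(msg, class = "motorpheno_design_error", ...)

# Signal used wherever an operation yields "no result" rather than a
# number (e.g. all windows gated out, no mobile frames).
warn_empty <- function(msg) warn(msg, class = "motorpheno_empty_result")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort_param(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Maximal runs of a logical vector; returns tibble(start_idx, end_idx, value).
runs_of <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  tibble(start_idx = end - r$lengths + 1L, end_idx = end, value = r$values)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
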