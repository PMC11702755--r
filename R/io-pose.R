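#' Construct a validated pose track
#'
#' A `pose_track` is a long tibble with one row per frame and bodypart:
#' columns `frame` (0-based), `time` (seconds), `bodypart`, `x`, `y` (pixels)
#' and `likelihood` (0-1), with the frame rate, pixel calibration and arena
#' carried as attributes. The open-field skeleton of the study has seven
#' parts (nose, ears, spine1-3, tail) tracked at 30 Hz with spine2 as the
#' centroid; the cylinder test tracks two parts (sensor, nose).
#'
#' @param df Tibble with columns `frame`, `bodypart`, `x`, `y`, `likelihood`
#'   and optionally `time`.
#' @param frame_rate Frames per second (nominal 30).
#' @param px_per_cm Pixel-to-centimetre calibration, > 0. The default preset
#'   assumes a 40 cm arena spanning the image width.
#' @param arena `"open_field"` or `"cylinder"`.
#' @param animal_id Optional identifier.
#'
#' @return A tibble of class `pose_track`.
#' @export
pose_track <- function(df, frame_rate = 30, px_per_cm,
                       arena = c("open_field", "cylinder"),
                       animal_id = NA_character_) {
  arena <- match.arg(arena)
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(px_per_cm, "px_per_cm", positive = TRUE)
  need <- c("frame", "bodypart", "x", "y", "likelihood")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("Pose table lacks column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(df$likelihood < 0 | df$likelihood > 1, na.rm = TRUE)) {
    abort_format("`likelihood` must lie in [0, 1].")
  }
  if (!"time" %in% names(df)) df$time <- df$frame / frame_rate
  ft <- sort(unique(df$time))
  if (length(ft) > 1 && any(diff(ft) <= 0)) {
    abort_format("Frame times must be strictly increasing.")
  }
  out <- as_tibble(df[, c("frame", "time", "bodypart", "x", "y", "likelihood")])
  out <- arrange(out, .data$frame, .data$bodypart)
  structure(out,
            frame_rate = frame_rate, px_per_cm = px_per_cm, arena = arena,
            animal_id = animal_id,
            class = c("pose_track", class(out)))
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames x %d bodyparts @ %g Hz, %s arena, %.3g px/cm\n",
              length(unique(x$frame)), length(unique(x$bodypart)),
              attr(x, "frame_rate"), attr(x, "arena"), attr(x, "px_per_cm")))
  NextMethod()
}

looks_like_dlc <- function(path) {
  first <- readr::read_lines(path, n_max = 2, progress = FALSE)
  grepl("^scorer", first[1]) ||
    (length(first) > 1 && grepl("^bodyparts", first[2]))
}

#' Read a pose-estimation CSV
#'
#' Two dialects are supported: `dlc_multiheader`, the standard DeepLabCut
#' export with three header rows (scorer / bodyparts / coords) followed by
#' per-frame `x, y, likelihood` triplets; and `flat`, a single-header table
#' `frame, <part>_x, <part>_y, <part>_p`.
#'
#' @param path CSV path.
#' @param dialect `"dlc_multiheader"` or `"flat"`.
#' @param frame_rate,px_per_cm,arena,animal_id Passed to [pose_track()].
#' @return A [pose_track()].
#' @export
read_pose_csv <- function(path, dialect = c("dlc_multiheader", "flat"),
                          frame_rate = 30, px_per_cm,
                          arena = c("open_field", "cylinder"),
                          animal_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "dlc_multiheader" && !looks_like_dlc(path)) {
    abort_format(sprintf(
      "%s does not start with DeepLabCut's scorer/bodyparts headers; try dialect = 'flat'.",
      path))
  }
  if (dialect == "flat" && looks_like_dlc(path)) {
    abort_format(sprintf(
      "%s looks like a DeepLabCut multi-header export; try dialect = 'dlc_multiheader'.",
      path))
  }
  if (dialect == "dlc_multiheader") {
    hdr <- strsplit(readr::read_lines(path, n_max = 3, progress = FALSE), ",")
    parts <- hdr[[2]][-1]
    coords <- hdr[[3]][-1]
    raw <- readr::read_csv(path, skip = 3, col_names = c("frame", paste0("V", seq_along(parts))),
                           show_col_types = FALSE, progress = FALSE)
    long <- tibble(
      frame = rep(raw$frame, times = length(parts)),
      bodypart = rep(parts, each = nrow(raw)),
      coord = rep(coords, each = nrow(raw)),
      value = unlist(raw[, -1], use.names = FALSE)
    )
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"frame" %in% names(raw)) abort_format("Flat pose CSV needs a `frame` column.")
    value_cols <- setdiff(names(raw), c("frame", "time"))
    m <- stringr::str_match(value_cols, "^(.*)_(x|y|p)$")
    if (any(is.na(m[, 1]))) {
      abort_format(sprintf("Column(s) not of the form <part>_{x,y,p}: %s.",
                           paste(value_cols[is.na(m[, 1])], collapse = ", ")))
    }
    long <- tibble(
      frame = rep(raw$frame, times = length(value_cols)),
      bodypart = rep(m[, 2], each = nrow(raw)),
      coord = rep(ifelse(m[, 3] == "p", "likelihood", m[, 3]), each = nrow(raw)),
      value = unlist(raw[, value_cols], use.names = FALSE)
    )
  }
  have <- distinct(long, .data$bodypart, .data$coord) |>
    count(.data$bodypart) |>
    filter(.data$n < 3)
  if (nrow(have)) {
    abort_format(sprintf("Bodypart(s) missing an x, y or likelihood column: %s.",
                         paste(have$bodypart, collapse = ", ")))
  }
  wide <- pivot_wider(long, names_from = "coord", values_from = "value")
  pose_track(wide, frame_rate = frame_rate, px_per_cm = px_per_cm,
             arena = arena, animal_id = animal_id)
}

#' Write a pose track to CSV
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @param dialect `"dlc_multiheader"` (DeepLabCut three-header layout) or
#'   `"flat"`.
#' @param scorer Scorer label for the DeepLabCut header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, dialect = c("dlc_multiheader", "flat"),
                           scorer = "motorpheno") {
  dialect <- match.arg(dialect)
  parts <- unique(track$bodypart)
  frames <- sort(unique(track$frame))
  cols <- list(frame = frames)
  for (p in parts) {
    sub <- arrange(filter(track, .data$bodypart == p), .data$frame)
    suffix <- if (dialect == "flat") c("x", "y", "p") else c("x", "y", "likelihood")
    cols[[paste0(p, "_", suffix[1])]] <- sub$x
    cols[[paste0(p, "_", suffix[2])]] <- sub$y
    cols[[paste0(p, "_", suffix[3])]] <- sub$likelihood
  }
  wide <- tibble::new_tibble(cols, nrow = length(frames))
  if (dialect == "dlc_multiheader") {
    lines <- c(
      paste(c("scorer", rep(scorer, 3L * length(parts))), collapse = ","),
      paste(c("bodyparts", rep(parts, each = 3)), collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))), collapse = ","),
      do.call(paste, c(lapply(wide, format_num_csv), list(sep = ",")))
    )
    readr::write_lines(lines, path)
  } else {
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

# Shortest round-trip decimal representation, readr-compatible.
format_num_csv <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    s
  }, character(1))
}
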