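#' Two-sided Mann-Whitney U test
#'
#' The group-comparison test used throughout the behavioral figures. The
#' exact null distribution is used when the combined sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with
#' midranks, tie-corrected variance and continuity correction is used. The
#' method actually applied is recorded in the result.
#'
#' @param group_a,group_b Numeric vectors (each n >= 3).
#' @return A one-row tibble of class `group_comparison`: `statistic` (U of
#'   `group_a`), `p_two_sided`, `n1`, `n2`, `direction` (sign of the
#'   location shift of `group_a` relative to `group_b`), `method`.
#' @export
mannwhitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort_input("Both groups must be non-empty.")
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort_input("Each group needs at least 3 observations.")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n1 + n2) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  shift <- u - n1 * n2 / 2
  tibble(statistic = u,
         p_two_sided = min(wt$p.value, 1),
         n1 = n1, n2 = n2,
         direction = sign(shift),
         method = if (exact) "exact" else "normal_tie_corrected") |>
    structure(class = c("group_comparison", class(tibble())))
}

#' Tracing fraction-table parameters
#'
#' Thresholds of the monosynaptic-input summary: a brain region is reported
#' when its pooled labeled-cell count exceeds `min_region_cells` and its
#' mean per-animal input fraction exceeds `min_fraction` (the study's
#' "more than 200 cells" and "greater than 0.2% of the total input"). The
#' two thresholds are independent parameters applied as a conjunction.
#'
#' @param min_region_cells Pooled-count threshold.
#' @param min_fraction Mean-fraction threshold.
#' @param fraction_scope `"group_mean"` filters on the mean fraction across
#'   animals; `"per_animal"` requires every animal to exceed it.
#' @return A list of class `tracing_params`.
#' @export
tracing_params <- function(min_region_cells = 200, min_fraction = 0.002,
                           fraction_scope = c("group_mean", "per_animal")) {
  fraction_scope <- match.arg(fraction_scope)
  if (min_region_cells < 0 || min_fraction < 0) abort_param("Thresholds must be >= 0.")
  structure(list(min_region_cells = min_region_cells,
                 min_fraction = min_fraction, fraction_scope = fraction_scope),
            class = c("tracing_params", "list"))
}

region_fractions <- function(counts, modality) {
  df <- filter(as_tibble(counts), .data$modality == !!modality)
  if (!nrow(df)) abort_input(sprintf("No rows with modality '%s'.", modality))
  if (!"hemisphere" %in% names(df)) df$hemisphere <- "both"
  df <- df |>
    group_by(.data$animal_id, .data$hemisphere) |>
    mutate(total = sum(.data$count)) |>
    ungroup()
  empty <- unique(df$animal_id[df$total == 0])
  if (length(empty)) {
    warn(sprintf("Animal(s) with zero total excluded: %s.",
                 paste(empty, collapse = ", ")))
    df <- filter(df, .data$total > 0)
  }
  mutate(df, fraction = .data$count / .data$total)
}

#' Monosynaptic input fractions per brain region
#'
#' Per animal (and hemisphere, when a `hemisphere` column is present) each
#' region's fraction of all labeled input cells; regions are retained when
#' their pooled count exceeds `min_region_cells` and their mean fraction
#' exceeds `min_fraction`, and are reported sorted by mean fraction.
#'
#' @param counts A [region_counts()] table (modality `input_cells`).
#' @param params A [tracing_params()].
#' @return Tibble with `hemisphere`, `region_acronym`, `n_animals`,
#'   `pooled_count`, `mean_fraction`, `sem_fraction`, sorted by
#'   `mean_fraction` (descending); per-animal fractions in attribute
#'   `per_animal`.
#' @export
region_input_fractions <- function(counts, params = tracing_params()) {
  per <- region_fractions(counts, "input_cells")
  grp <- per |>
    group_by(.data$hemisphere, .data$region_acronym) |>
    summarise(n_animals = dplyr::n_distinct(.data$animal_id),
              pooled_count = sum(.data$count),
              mean_fraction = mean(.data$fraction),
              sem_fraction = sd(.data$fraction) / sqrt(n()),
              min_animal_fraction = min(.data$fraction),
              .groups = "drop")
  frac_ok <- if (params$fraction_scope == "group_mean") {
    grp$mean_fraction > params$min_fraction
  } else {
    grp$min_animal_fraction > params$min_fraction
  }
  out <- grp[grp$pooled_count > params$min_region_cells & frac_ok, ] |>
    select(-"min_animal_fraction") |>
    arrange(.data$hemisphere, dplyr::desc(.data$mean_fraction))
  structure(out, per_animal = per, class = class(out))
}

#' Output (neurite) fractions per brain region
#'
#' Per animal each region's fraction of the total neurite signal, and the
#' group mean with its standard error; no region filter is applied.
#'
#' @param counts A [region_counts()] table (modality `output_neurites`).
#' @return Tibble with `hemisphere`, `region_acronym`, `n_animals`,
#'   `mean_fraction`, `sem_fraction`; per-animal fractions in attribute
#'   `per_animal`.
#' @export
region_output_fractions <- function(counts) {
  per <- region_fractions(counts, "output_neurites")
  out <- per |>
    group_by(.data$hemisphere, .data$region_acronym) |>
    summarise(n_animals = dplyr::n_distinct(.data$animal_id),
              mean_fraction = mean(.data$fraction),
              sem_fraction = sd(.data$fraction) / sqrt(n()),
              .groups = "drop") |>
    arrange(.data$hemisphere, dplyr::desc(.data$mean_fraction))
  structure(out, per_animal = per, class = class(out))
}

#' Assemble a cohort report directory
#'
#' Writes every supplied result table as CSV plus a JSON index listing the
#' produced files. A pure function of its inputs: re-running with the same
#' tables produces byte-identical output.
#'
#' @param results Named list of data frames (and/or `trend_fit` objects,
#'   which are written via [glance()]).
#' @param dir Output directory (created if needed).
#' @return The index path, invisibly.
#' @export
assemble_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "trend_fit")) obj <- glance(obj)
    if (!is.data.frame(obj)) next
    obj <- as_tibble(obj)
    obj <- obj[, !vapply(obj, is.list, logical(1)), drop = FALSE]
    f <- paste0(nm, ".csv")
    readr::write_csv(obj, file.path(dir, f), progress = FALSE)
    files <- c(files, f)
  }
  index <- list(tables = as.list(files), n_tables = length(files))
  path <- file.path(dir, "index.json")
  jsonlite::write_json(index, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
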