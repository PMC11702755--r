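#' Construct a validated per-cell composition table
#'
#' One row per nucleus/cell with its donor mouse and cluster assignment:
#' columns `cell_id`, `mouse_id`, `genotype` (`case`/`control`), `sex`
#' (`F`/`M`), `age_group` (weeks), `batch`, `cluster`. Every mouse must map
#' to exactly one (genotype, sex, age_group) combination.
#'
#' @param df Data frame with the six required columns.
#' @return A tibble of class `cell_table`.
#' @export
cell_table <- function(df) {
  need <- c("cell_id", "mouse_id", "genotype", "sex", "age_group", "batch", "cluster")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("Cell table lacks column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  bad_geno <- setdiff(unique(df$genotype), c("case", "control"))
  if (length(bad_geno)) {
    abort_format(sprintf("`genotype` must be 'case' or 'control'; found: %s.",
                         paste(bad_geno, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad_sex)) {
    abort_format(sprintf("`sex` must be 'F' or 'M'; found: %s.",
                         paste(bad_sex, collapse = ", ")))
  }
  meta <- distinct(df, .data$mouse_id, .data$genotype, .data$sex, .data$age_group)
  dup <- meta$mouse_id[duplicated(meta$mouse_id)]
  if (length(dup)) {
    abort(sprintf("Mouse/mice with inconsistent metadata rows: %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "motorpheno_consistency_error")
  }
  out <- as_tibble(df[, need])
  structure(out, class = c("cell_table", class(out)))
}

#' Read a per-cell composition CSV/TSV
#'
#' Rows lacking a cluster label are rejected and counted in the attached
#' load report rather than silently kept.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, else CSV.
#' @param quiet Suppress the summary message.
#' @return A [cell_table()] with attribute `load_report`.
#' @export
read_cell_table <- function(path, quiet = FALSE) {
  reader <- if (grepl("\\.(tsv|txt)$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  n_in <- nrow(df)
  keep <- !is.na(df$cluster) & df$cluster != ""
  df <- df[keep, , drop = FALSE]
  tab <- cell_table(df)
  report <- list(rows_read = n_in, rows_kept = nrow(tab),
                 rows_rejected_no_cluster = n_in - nrow(tab))
  attr(tab, "load_report") <- report
  if (!quiet) {
    by_geno <- count(tab, .data$genotype)
    inform(sprintf(
      "Loaded %d cells (%d rejected without cluster label): %d mice, %d clusters; cells per genotype: %s.",
      nrow(tab), report$rows_rejected_no_cluster,
      length(unique(tab$mouse_id)), length(unique(tab$cluster)),
      paste(sprintf("%s=%d", by_geno$genotype, by_geno$n), collapse = ", ")))
  }
  tab
}

#' Write a cell composition table to CSV
#' @param tab A [cell_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  readr::write_csv(as_tibble(tab), path, progress = FALSE)
  invisible(path)
}

#' Construct a validated region count table
#'
#' Per-animal labeled-cell or neurite counts assigned to brain-atlas region
#' acronyms: columns `animal_id`, `region_acronym`, `count` (>= 0) and
#' `modality` (`input_cells` for rabies-labeled presynaptic neurons,
#' `output_neurites` for axonal signal). An optional `hemisphere` column
#' (`ipsi`/`contra`) splits input fractions by side.
#'
#' @param df Data frame with the required columns.
#' @return A tibble of class `region_counts`.
#' @export
region_counts <- function(df) {
  need <- c("animal_id", "region_acronym", "count", "modality")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("Region count table lacks column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(df$count < 0, na.rm = TRUE)) abort_format("Counts must be >= 0.")
  bad_mod <- setdiff(unique(df$modality), c("input_cells", "output_neurites"))
  if (length(bad_mod)) {
    abort_format(sprintf("Unknown modality value(s): %s.", paste(bad_mod, collapse = ", ")))
  }
  key <- c("animal_id", "modality", "region_acronym",
           intersect("hemisphere", names(df)))
  if (anyDuplicated(df[, key])) {
    abort_format("Region acronyms must be unique per animal (and hemisphere).")
  }
  out <- as_tibble(df)
  structure(out, class = c("region_counts", class(out)))
}

#' Read a region count CSV
#' @param path CSV path.
#' @return A [region_counts()] table.
#' @export
read_region_counts <- function(path) {
  region_counts(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_region_counts
#' @param counts A [region_counts()] table.
#' @export
write_region_counts <- function(counts, path) {
  readr::write_csv(as_tibble(counts), path, progress = FALSE)
  invisible(path)
}
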