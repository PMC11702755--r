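#' Differential-abundance parameters
#'
#' Settings of the per-cluster mixed-effects logistic membership model:
#' cell-level membership in a cluster is regressed on the case/control
#' condition with sex as a fixed covariate and a per-individual (mouse)
#' random intercept; the condition p-value comes from a likelihood-ratio
#' test of the full against the condition-dropped model; clusters are
#' FDR-adjusted with Benjamini-Hochberg.
#'
#' @param condition_var Column holding the tested status (default
#'   `genotype`; use `age_group` for within-genotype age contrasts).
#' @param condition_levels `c(reference, test)` levels of the condition.
#' @param covariates Fixed-effect covariate columns (default sex; `batch`
#'   may be added, but never the tested condition).
#' @param random_intercept Grouping column for the random intercept, or
#'   `NULL` to constrain its variance to zero (plain logistic regression).
#' @param fdr_alpha Significance level on the FDR-adjusted p.
#' @param ci_level Wald confidence level for the log odds ratio.
#' @param min_cells_per_cluster Clusters with fewer total cells are skipped.
#' @param significance_rule `"ci_excludes_zero"` requires the CI to exclude
#'   0 in addition to `fdr_q < fdr_alpha`; `"nonzero_estimate"` is the
#'   literal (vacuous for any nonzero estimate) published rule.
#' @return A list of class `abundance_params`.
#' @export
abundance_params <- function(condition_var = "genotype",
                             condition_levels = c("control", "case"),
                             covariates = "sex",
                             random_intercept = "mouse_id",
                             fdr_alpha = 0.05, ci_level = 0.95,
                             min_cells_per_cluster = 20,
                             significance_rule = c("ci_excludes_zero",
                                                   "nonzero_estimate")) {
  significance_rule <- match.arg(significance_rule)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort_param("`fdr_alpha` must lie in (0, 1).")
  if (condition_var %in% covariates) {
    abort_param("The tested condition cannot also be a covariate.")
  }
  structure(list(condition_var = condition_var,
                 condition_levels = condition_levels,
                 covariates = covariates, random_intercept = random_intercept,
                 fdr_alpha = fdr_alpha, ci_level = ci_level,
                 min_cells_per_cluster = min_cells_per_cluster,
                 significance_rule = significance_rule),
            class = c("abundance_params", "list"))
}

# Aggregate cells to one binomial row per mouse: (in-cluster, out-of-cluster)
# counts with the mouse's metadata. Likelihood-equivalent to the cell-level
# Bernoulli model and far faster to fit.
aggregate_membership <- function(table, cluster, params) {
  meta_cols <- unique(c("mouse_id", params$condition_var, params$covariates))
  table |>
    filter(.data[[params$condition_var]] %in% params$condition_levels) |>
    group_by(across(dplyr::all_of(meta_cols))) |>
    summarise(y = sum(.data$cluster == !!cluster), n = n(), .groups = "drop") |>
    mutate(condition = factor(.data[[params$condition_var]],
                              levels = params$condition_levels))
}

#' Fit the membership model for one cluster
#'
#' @param table A [cell_table()] (already subset to the contrast of
#'   interest, e.g. one age group for a case-vs-control test).
#' @param cluster Cluster label to test.
#' @param params An [abundance_params()].
#' @return A one-row tibble: `cluster`, `log_or` (natural-log odds ratio of
#'   membership for the test condition), `ci_low`, `ci_high`, `p_value`
#'   (likelihood-ratio test), `n_cells`, `model` (`"glmer"` or `"glm"`),
#'   `converged`, `note`.
#' @export
fit_cluster_model <- function(table, cluster, params = abundance_params()) {
  agg <- aggregate_membership(table, cluster, params)
  n_cells <- sum(agg$y)
  row <- tibble(cluster = cluster, log_or = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_, n_cells = n_cells,
                model = NA_character_, converged = FALSE, note = NA_character_)
  if (length(unique(agg$condition)) < 2L) {
    row$note <- "only one condition level present"
    return(row)
  }
  if (n_cells < params$min_cells_per_cluster) {
    row$note <- sprintf("fewer than %d cells", params$min_cells_per_cluster)
    return(row)
  }
  by_cond <- agg |> group_by(.data$condition) |> summarise(y = sum(.data$y))
  if (any(by_cond$y == 0)) {
    # complete separation: the cluster is absent in one condition; report
    # the direction qualitatively rather than a divergent estimate
    absent <- as.character(by_cond$condition[by_cond$y == 0][1])
    row$model <- "separation"
    row$note <- sprintf(
      "cluster absent in condition '%s': qualitative %s in '%s'",
      absent,
      if (absent == params$condition_levels[2]) "depletion" else "enrichment",
      params$condition_levels[2])
    return(row)
  }
  covs <- intersect(params$covariates, names(agg))
  drop_cov <- covs[vapply(covs, function(cv) length(unique(agg[[cv]])) < 2L, logical(1))]
  covs <- setdiff(covs, drop_cov)
  rhs_cov <- if (length(covs)) paste(c("", covs), collapse = " + ") else ""
  use_ri <- !is.null(params$random_intercept) &&
    length(unique(agg[[params$random_intercept]])) > length(unique(agg$condition))
  fit <- NULL
  if (use_ri) {
    f_full <- as.formula(paste0("cbind(y, n - y) ~ condition", rhs_cov,
                                " + (1 | ", params$random_intercept, ")"))
    f_red <- as.formula(paste0("cbind(y, n - y) ~ 1", rhs_cov,
                               " + (1 | ", params$random_intercept, ")"))
    fit <- tryCatch({
      full <- suppressWarnings(suppressMessages(
        lme4::glmer(f_full, data = agg, family = binomial)))
      red <- suppressWarnings(suppressMessages(
        lme4::glmer(f_red, data = agg, family = binomial)))
      lrt <- anova(full, red)
      # a boundary (singular) fit is a legitimate zero-variance estimate,
      # not a convergence failure
      msgs <- full@optinfo$conv$lme4$messages
      list(full = full, p = lrt$`Pr(>Chisq)`[2],
           est = unname(lme4::fixef(full)[2]),
           se = sqrt(diag(as.matrix(vcov(full)))[2]),
           model = "glmer",
           ok = full@optinfo$conv$opt == 0 &&
             all(grepl("boundary \\(singular\\)", unlist(msgs))))
    }, error = function(e) NULL)
  }
  if (is.null(fit)) {
    # random-intercept variance constrained to zero (degenerate design or
    # glmer failure): plain logistic regression, LRT against the reduced fit
    f_full <- as.formula(paste0("cbind(y, n - y) ~ condition", rhs_cov))
    f_red <- as.formula(paste0("cbind(y, n - y) ~ 1", rhs_cov))
    full <- glm(f_full, data = agg, family = binomial)
    red <- glm(f_red, data = agg, family = binomial)
    fit <- list(full = full,
                p = pchisq(red$deviance - full$deviance, df = 1, lower.tail = FALSE),
                est = unname(coef(full)[2]),
                se = sqrt(diag(vcov(full))[2]),
                model = if (use_ri) "glm_fallback" else "glm",
                ok = full$converged)
  }
  zq <- qnorm(1 - (1 - params$ci_level) / 2)
  row$log_or <- fit$est
  row$ci_low <- fit$est - zq * fit$se
  row$ci_high <- fit$est + zq * fit$se
  row$p_value <- fit$p
  row$model <- fit$model
  row$converged <- isTRUE(fit$ok)
  row
}

#' Differential cell-type abundance across clusters
#'
#' Fits the membership model for every cluster, applies Benjamini-Hochberg
#' FDR adjustment across the successfully fitted clusters, and flags
#' significance. Non-converged or separated clusters are excluded from the
#' FDR family with a warning.
#'
#' @param table A [cell_table()], subset to the cohorts being contrasted.
#' @param params An [abundance_params()].
#' @return A tibble of class `abundance_result` with one row per cluster:
#'   `cluster`, `log_or`, `ci_low`, `ci_high`, `p_value`, `fdr_q`,
#'   `significant`, `n_cells`, `model`, `note`.
#' @export
differential_abundance <- function(table, params = abundance_params()) {
  clusters <- sort(unique(table$cluster))
  res <- map_dfr(clusters, function(k) fit_cluster_model(table, k, params))
  fitted <- res$converged & !is.na(res$p_value)
  if (sum(fitted) < 2L) {
    warn_empty("Fewer than two clusters fitted successfully.")
  }
  if (any(!fitted)) {
    warn(sprintf("%d cluster(s) excluded from the FDR family: %s.",
                 sum(!fitted), paste(res$cluster[!fitted], collapse = ", ")))
  }
  res$fdr_q <- NA_real_
  res$fdr_q[fitted] <- p.adjust(res$p_value[fitted], method = "BH")
  effect_ok <- if (params$significance_rule == "ci_excludes_zero") {
    res$ci_low > 0 | res$ci_high < 0
  } else {
    res$log_or != 0
  }
  res$significant <- !is.na(res$fdr_q) & res$fdr_q < params$fdr_alpha &
    !is.na(res$log_or) & effect_ok
  structure(res, params = params,
            class = c("abundance_result", class(res)))
}

#' Per-mouse cluster proportions
#'
#' @param table A [cell_table()].
#' @return Tibble with one row per mouse and cluster: metadata, `n_cells`,
#'   `proportion` (zero-count clusters reported as 0; proportions per mouse
#'   sum to 1). Mice with zero cells are excluded with a warning.
#' @export
proportion_table <- function(table) {
  clusters <- sort(unique(table$cluster))
  meta <- distinct(table, .data$mouse_id, .data$genotype, .data$sex,
                   .data$age_group)
  counts <- count(table, .data$mouse_id, .data$cluster, name = "n_cells")
  out <- tidyr::expand_grid(meta, cluster = clusters) |>
    left_join(counts, by = c("mouse_id", "cluster")) |>
    mutate(n_cells = ifelse(is.na(.data$n_cells), 0L, .data$n_cells)) |>
    group_by(.data$mouse_id) |>
    mutate(total = sum(.data$n_cells),
           proportion = .data$n_cells / .data$total) |>
    ungroup()
  empty <- unique(out$mouse_id[out$total == 0])
  if (length(empty)) {
    warn(sprintf("Mouse/mice with zero cells excluded: %s.",
                 paste(empty, collapse = ", ")))
    out <- filter(out, .data$total > 0)
  }
  select(out, -"total")
}

#' Two-way ANOVA on cluster proportions
#'
#' For each cluster, fits proportion ~ genotype * age (type-II ANOVA) and
#' reports the genotype-by-age interaction p-value — the statistic used to
#' ask whether a subtype's share declines differently in cases than in
#' controls as animals age — followed by Tukey HSD over the genotype-by-age
#' cell means.
#'
#' @param proportions Output of [proportion_table()].
#' @return A tibble of class `proportion_anova` with one row per cluster:
#'   `cluster`, `interaction_F`, `interaction_p`, and a list-column `tukey`
#'   of pairwise comparisons.
#' @export
anova_proportions <- function(proportions) {
  cells <- proportions |>
    distinct(.data$genotype, .data$age_group, .data$mouse_id) |>
    count(.data$genotype, .data$age_group)
  full_grid <- tidyr::expand_grid(genotype = unique(proportions$genotype),
                                  age_group = unique(proportions$age_group))
  have <- left_join(full_grid, cells, by = c("genotype", "age_group"))
  if (any(is.na(have$n)) || any(have$n < 2)) {
    abort_design("Each genotype-by-age cell needs at least 2 mice.")
  }
  map_dfr(sort(unique(proportions$cluster)), function(k) {
    d <- proportions |>
      filter(.data$cluster == k) |>
      mutate(genotype = factor(.data$genotype),
             age = factor(.data$age_group))
    m <- lm(proportion ~ genotype * age, data = d)
    res <- tryCatch({
      a2 <- car::Anova(m, type = 2)
      i <- grep("genotype:age", rownames(a2))
      list(f = a2[i, "F value"], p = a2[i, "Pr(>F)"])
    }, error = function(e) {
      # zero residual variance (noise-free input): decide from the
      # interaction sum of squares directly
      a1 <- anova(m)
      ss_i <- a1["genotype:age", "Sum Sq"]
      if (ss_i > 1e-12 * sum(a1$`Sum Sq`)) list(f = Inf, p = 0) else list(f = 0, p = 1)
    })
    tk <- TukeyHSD(aov(proportion ~ genotype:age, data = d))
    tk_tab <- as_tibble(tk[[1]], rownames = "contrast")
    tibble(cluster = k,
           interaction_F = res$f,
           interaction_p = res$p,
           tukey = list(tk_tab))
  }) |>
    structure(class = c("proportion_anova", class(tibble())))
}
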