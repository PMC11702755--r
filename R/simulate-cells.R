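#' Parameters for the synthetic cell-composition generator
#'
#' Cohorts mirror the study design: at each age group, `n_mice` mice per
#' genotype split evenly by sex (the study profiled 4 female + 4 male per
#' time point). Each mouse's cluster probabilities come from a
#' multinomial-logit model: per-cluster baseline log-odds, plus a genotype
#' effect (depletion negative) on affected clusters, a sex effect, and an
#' independent per-individual random intercept on designated clusters
#' (logit-normal mixture). Cells per mouse are negative-binomial to mimic
#' unequal nuclear capture.
#'
#' Because only the targeted cluster's logit is shifted, the injected
#' genotype effect equals the cluster's one-vs-rest log-odds difference
#' exactly, which is what the abundance model estimates.
#'
#' @param n_mice Mice per genotype within an age group (even; half F, half M).
#' @param age_groups Ages in weeks.
#' @param baseline_logodds Named numeric vector of per-cluster baseline
#'   log-odds (softmax-normalized to proportions).
#' @param genotype_effect Named vector of log-odds shifts applied to case
#'   mice (names must be clusters).
#' @param sex_effect Named vector of log-odds shifts applied to male mice.
#' @param ri_sd Per-individual random-intercept standard deviation (log-odds).
#' @param ri_clusters Clusters receiving the random intercept (default all).
#' @param cells_per_mouse `c(mean, size)` of the negative-binomial cell count.
#' @param batches Number of batches (mice assigned round-robin).
#' @param seed Generator seed.
#' @return A list of class `composition_sim_params`.
#' @export
composition_sim_params <- function(
    n_mice = 8, age_groups = c(8, 16, 24),
    baseline_logodds = c(Sox6 = 1.0, Anxa1 = 0.4, Calb1 = 0.6, Gad2 = 0.0,
                         Cck = -0.3, Megf11 = -0.6, Synpr = -0.9, Vip = -1.2),
    genotype_effect = c(Sox6 = 0),
    sex_effect = c(Sox6 = 0),
    ri_sd = 0.25, ri_clusters = NULL,
    cells_per_mouse = c(mean = 1000, size = 10),
    batches = 2, seed = 1L) {
  clusters <- names(baseline_logodds)
  if (is.null(clusters) || any(clusters == "")) {
    abort_param("`baseline_logodds` must be a fully named vector.")
  }
  for (eff in list(genotype_effect = genotype_effect, sex_effect = sex_effect)) {
    unknown <- setdiff(names(eff), clusters)
    if (length(unknown)) {
      abort_param(sprintf("Effect references unknown cluster(s): %s.",
                          paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(ri_clusters) && length(setdiff(ri_clusters, clusters))) {
    abort_param("`ri_clusters` references unknown clusters.")
  }
  if (n_mice %% 2 != 0) abort_param("`n_mice` must be even (half F, half M).")
  p <- list(n_mice = n_mice, age_groups = age_groups,
            baseline_logodds = baseline_logodds,
            genotype_effect = genotype_effect, sex_effect = sex_effect,
            ri_sd = ri_sd, ri_clusters = ri_clusters %||% clusters,
            cells_per_mouse = cells_per_mouse, batches = batches, seed = as.integer(seed))
  structure(p, class = c("composition_sim_params", "list"))
}

#' Simulate a per-cell composition cohort
#'
#' @param params A [composition_sim_params()].
#' @return A list with `table` (a [cell_table()]) and `truth` (per-mouse
#'   cluster probabilities, realized random intercepts, parameters).
#' @export
simulate_cell_composition <- function(params = composition_sim_params()) {
  p <- params
  clusters <- names(p$baseline_logodds)
  with_seed(p$seed, {
    mice <- tidyr::expand_grid(
      age_group = p$age_groups,
      genotype = c("control", "case"),
      idx = seq_len(p$n_mice)
    ) |>
      mutate(sex = ifelse(.data$idx <= p$n_mice / 2, "F", "M"),
             mouse_id = sprintf("m_%s_%02dw_%02d", .data$genotype,
                                .data$age_group, .data$idx),
             batch = sprintf("b%d", (seq_len(n()) - 1L) %% p$batches + 1L))
    eff_vec <- function(eff) {
      v <- setNames(rep(0, length(clusters)), clusters)
      v[names(eff)] <- eff
      v
    }
    g_eff <- eff_vec(p$genotype_effect)
    s_eff <- eff_vec(p$sex_effect)
    rows <- vector("list", nrow(mice))
    probs <- vector("list", nrow(mice))
    ri_all <- vector("list", nrow(mice))
    for (i in seq_len(nrow(mice))) {
      m <- mice[i, ]
      eta <- p$baseline_logodds
      if (m$genotype == "case") eta <- eta + g_eff
      if (m$sex == "M") eta <- eta + s_eff
      ri <- setNames(rep(0, length(clusters)), clusters)
      if (p$ri_sd > 0) {
        ri[p$ri_clusters] <- rnorm(length(p$ri_clusters), 0, p$ri_sd)
      }
      eta <- eta + ri
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      n_cells <- rnbinom(1, size = p$cells_per_mouse[["size"]],
                         mu = p$cells_per_mouse[["mean"]])
      n_cells <- max(n_cells, 1L)
      counts <- as.vector(rmultinom(1, n_cells, pr))
      rows[[i]] <- tibble(
        cell_id = sprintf("%s_c%05d", m$mouse_id, seq_len(n_cells)),
        mouse_id = m$mouse_id, genotype = m$genotype, sex = m$sex,
        age_group = m$age_group, batch = m$batch,
        cluster = rep(clusters, counts)
      )
      probs[[i]] <- tibble(mouse_id = m$mouse_id, cluster = clusters,
                           prob = pr)
      ri_all[[i]] <- tibble(mouse_id = m$mouse_id, cluster = clusters, ri = ri)
    }
    tab <- cell_table(bind_rows(rows))
    truth <- list(params = p, mice = mice,
                  probabilities = bind_rows(probs),
                  random_intercepts = bind_rows(ri_all),
                  genotype_effect = g_eff, sex_effect = s_eff)
    list(table = tab, truth = truth)
  })
}

#' Named simulation presets
#'
#' * `cohort` — the full study design: three age groups, amplitude-scheduled
#'   tremor, bout-structured trajectories and a null composition cohort.
#' * `null` — no tremor, no composition effects.
#' * `depletion` — a single cluster (Sox6) depleted with log-odds effect
#'   -1.5 in case mice.
#'
#' @param preset Preset name.
#' @param seed Seed applied to every generator in the preset.
#' @return A named list of parameter objects.
#' @export
sim_preset <- function(preset = c("cohort", "null", "depletion"), seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    accel = tremor_sim_params(duration = 120, seed = seed),
    pose = bout_sim_params(duration = 1500, seed = seed),
    composition = composition_sim_params(seed = seed)
  )
  switch(preset,
    cohort = base,
    null = {
      base$accel$tremor_amp$amp <- c(0, 0, 0)
      base$composition$genotype_effect <- c(Sox6 = 0)
      base
    },
    depletion = {
      base$composition$genotype_effect <- c(Sox6 = -1.5)
      base
    })
}
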