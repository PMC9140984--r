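#' Configure an end-to-end synthetic analysis run
#'
#' Bundles the cohort generator settings with every stage's parameters: QC
#' thresholds, motion-correction mode, developmental-model engine, FDR level,
#' permutation/null counts, transcriptomic planting, and case-control
#' colocation. A single master seed deterministically derives all per-stage
#' seeds, so a run is reproducible bit-for-bit.
#'
#' @param cohort a [cohort_config()]; its seed is overridden by a seed derived
#'   from `seed`.
#' @param mean_fd_max,max_fd_max scan QC thresholds (mm).
#' @param fd_mode motion-regression mode, `"pooled"` or `"by_sex"`.
#' @param use_gsr apply global signal regression to time series (timeseries
#'   mode only).
#' @param covariate optional per-scan covariate to residualise edges on after
#'   motion correction: `"icv"`, `"global_fc"` or `NULL`.
#' @param engine developmental-fit engine, `"ols"` or `"lme"`.
#' @param q_level FDR level for sex-difference significance.
#' @param n_perm spin/unconstrained permutation count.
#' @param n_null null-set count for enrichment.
#' @param expression_rho,module_size,n_genes,x_frac_module expression-panel
#'   planting (see [simulate_expression_panel()]).
#' @param cc_r_target,cc_effect,cc_n_cases,cc_n_controls case-control
#'   planting (see [simulate_casecontrol()]).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            mean_fd_max = 0.3, max_fd_max = 1.3,
                            fd_mode = "pooled",
                            use_gsr = FALSE,
                            covariate = NULL,
                            engine = "ols",
                            q_level = 0.05,
                            n_perm = 1000,
                            n_null = 1000,
                            expression_rho = 0.9, module_size = 100,
                            n_genes = 2000, x_frac_module = 0.5,
                            cc_r_target = 0.4, cc_effect = 1,
                            cc_n_cases = 50, cc_n_controls = 46,
                            seed = 1L) {
  structure(list(
    cohort = cohort, mean_fd_max = mean_fd_max, max_fd_max = max_fd_max,
    fd_mode = fd_mode, use_gsr = use_gsr, covariate = covariate,
    engine = engine, q_level = q_level, n_perm = n_perm, n_null = n_null,
    expression_rho = expression_rho, module_size = module_size,
    n_genes = n_genes, x_frac_module = x_frac_module,
    cc_r_target = cc_r_target, cc_effect = cc_effect,
    cc_n_cases = cc_n_cases, cc_n_controls = cc_n_controls,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: cohort simulation; scan QC; motion correction (and
#' optional covariate residualisation); global-FC age/sex model; per-sex
#' edgewise trajectory fits; maturational index, its sex difference with FDR
#' control, and developmental-mode classification; sex differences in
#' baseline and rate-of-change parameters; spin-ensemble construction;
#' expression-panel simulation, PLS1 with permutation/spin significance,
#' gene ranking, module enrichment and chromosome profile; case-control
#' degree-map simulation, t map and colocation with the sex-difference map.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: stage outputs are written as delimited
#'   tables plus a plain-text report and a JSON parameter echo.
#' @return A `maturind_run` list with every stage's result; see
#'   [glance.maturind_run()] for the headline numbers.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed_of <- function(k) derive_seed(config$seed, k)

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seed_of(10L)
  cohort <- simulate_cohort(cohort_cfg)
  meta <- cohort$metadata

  qc <- qc_scans(meta, config$mean_fd_max, config$max_fd_max)
  kept <- dplyr::filter(qc, .data$qc_pass)

  if (cohort_cfg$mode == "timeseries") {
    ts_list <- cohort$timeseries[kept$scan_id]
    ts_list <- purrr::map(ts_list, function(ts) {
      if (config$use_gsr) ts <- gsr(ts)
      normalize_timeseries(ts)
    })
    mats <- purrr::map(ts_list, fc_matrix)
    stack <- fc_stack_from_matrices(mats, provenance = list(gsr = config$use_gsr))
  } else {
    stack <- cohort$fc
    stack$values <- stack$values[kept$scan_id, , drop = FALSE]
    stack$scan_id <- kept$scan_id
  }

  stack <- motion_regress(stack, kept$mean_fd, mode = config$fd_mode,
                          sex = kept$sex)
  if (!is.null(config$covariate)) {
    cov_vals <- switch(config$covariate,
                       icv = kept$icv,
                       global_fc = global_fc(stack)$global_fc,
                       stop_maturind("unknown covariate '%s'", config$covariate))
    stack <- covariate_regress(stack, cov_vals, name = config$covariate)
  }

  gfc <- global_fc(stack)
  global_model <- global_fc_model(gfc, kept)

  fit_f <- fit_trajectories(stack, kept, "female", unit = "edge", engine = config$engine)
  fit_m <- fit_trajectories(stack, kept, "male", unit = "edge", engine = config$engine)
  mi_f <- maturational_index(fit_f)
  mi_m <- maturational_index(fit_m)
  dmi <- delta_mi(mi_f, mi_m, q_level = config$q_level)
  dmi <- classify_development(dmi)
  d_fc14 <- delta_param(fit_f, fit_m, "fc14", q_level = config$q_level)
  d_slope <- delta_param(fit_f, fit_m, "slope", q_level = config$q_level)

  atlas <- cohort$atlas
  ctx <- atlas$region[atlas$kind == "cortical"]
  sub <- atlas$region[atlas$kind == "subcortical"]
  coords <- simulate_sphere_coords(length(ctx), seed = seed_of(20L))
  spins <- spin_rotations(coords, n_perm = config$n_perm, seed = seed_of(21L),
                          subcortical = sub)
  dmi_map <- tibble::tibble(region = dmi$unit, value = dmi$delta)
  dmi_map_ctx <- dplyr::filter(dmi_map, .data$region %in% ctx)

  panel <- simulate_expression_panel(dmi_map_ctx, n_genes = config$n_genes,
                                     module_size = config$module_size,
                                     rho = config$expression_rho,
                                     x_frac_module = config$x_frac_module,
                                     seed = seed_of(30L))
  pls <- pls1(panel$expression, dmi_map_ctx)
  pls_sig <- pls1_significance(panel$expression, dmi_map_ctx, spins,
                               n_perm = config$n_perm, seed = seed_of(31L))
  ranking <- rank_genes(pls)
  module_genes <- panel$genes$gene[panel$genes$in_module]
  enrichment <- median_rank_enrichment(ranking, module_genes, panel$genes,
                                       n_null = config$n_null, seed = seed_of(32L))
  chrom <- chromosome_profile(ranking, panel$genes, n_null = config$n_null,
                              seed = seed_of(33L))

  cc <- simulate_casecontrol(dmi_map, effect = config$cc_effect,
                             r_target = config$cc_r_target,
                             n_cases = config$cc_n_cases,
                             n_controls = config$cc_n_controls,
                             seed = seed_of(40L))
  tmap <- degree_tmap(cc$degrees, cc$labels)
  colocation <- colocate_with_dmi(tmap, dmi_map, spins)

  run <- structure(list(
    config = config, cohort = cohort, qc = qc, stack = stack,
    global_model = global_model,
    fits = list(female = fit_f, male = fit_m),
    mi = list(female = mi_f, male = mi_m),
    dmi = dmi, d_fc14 = d_fc14, d_slope = d_slope,
    coords = coords, spins = spins,
    panel = panel, pls = pls, pls_significance = pls_sig,
    ranking = ranking, enrichment = enrichment, chromosome_profile = chrom,
    casecontrol = cc, tmap = tmap, colocation = colocation
  ), class = "maturind_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Headline numbers of a pipeline run
#'
#' @param x a `maturind_run`.
#' @param ... unused.
#' @return A one-row tibble: scan counts, global-FC sex t, significant-node
#'   counts and mode split, PLS variance explained and p values, module
#'   enrichment p, X-chromosome median rank, colocation r and p values.
#' @export
glance.maturind_run <- function(x, ...) {
  sex_t <- x$global_model$statistic[x$global_model$term == "sexmale"]
  modes <- table(x$dmi$mode)
  chrom_x <- dplyr::filter(x$chromosome_profile, .data$chromosome == "X")
  tibble::tibble(
    n_scans = nrow(x$qc),
    n_scans_retained = sum(x$qc$qc_pass),
    n_subjects = length(unique(x$qc$subject_id)),
    global_sex_t = sex_t,
    n_nodes = nrow(x$dmi),
    n_dmi_significant = sum(x$dmi$significant),
    n_female_more_disruptive = sum(x$dmi$mode == "female_more_disruptive"),
    n_female_less_conservative = sum(x$dmi$mode == "female_less_conservative"),
    pls_varexp = x$pls$varexp,
    pls_p_perm = x$pls_significance$p_perm,
    pls_p_spin = x$pls_significance$p_spin,
    module_enrichment_p = x$enrichment$p,
    module_enrichment_direction = x$enrichment$direction,
    chrX_median_rank = chrom_x$median_rank,
    chrX_p = chrom_x$p,
    colocation_r = x$colocation$r,
    colocation_p_spin = x$colocation$p_spin
  )
}

#' @export
print.maturind_run <- function(x, ...) {
  g <- glance(x)
  cat("<maturind_run>\n")
  cat(sprintf("  scans: %d retained of %d (%d subjects)\n",
              g$n_scans_retained, g$n_scans, g$n_subjects))
  cat(sprintf("  global FC sex effect (male - female): t = %.2f\n", g$global_sex_t))
  cat(sprintf("  sex difference in MI: %d / %d nodes FDR-significant (%d more disruptive, %d less conservative in females)\n",
              g$n_dmi_significant, g$n_nodes,
              g$n_female_more_disruptive, g$n_female_less_conservative))
  cat(sprintf("  PLS1: %.1f%% of variance in the sex-difference map (p_perm = %.3g, p_spin = %.3g)\n",
              100 * g$pls_varexp, g$pls_p_perm, g$pls_p_spin))
  cat(sprintf("  module enrichment: p = %.3g (%s); X chromosome median rank %.0f (p = %.3g)\n",
              g$module_enrichment_p, g$module_enrichment_direction,
              g$chrX_median_rank, g$chrX_p))
  cat(sprintf("  case-control colocation: r = %.2f (p_spin = %.3g)\n",
              g$colocation_r, g$colocation_p_spin))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  w(run$qc, "qc_log.tsv")
  w(run$global_model, "global_fc_model.tsv")
  w(tibble::as_tibble(run$fits$female), "fit_edges_female.tsv")
  w(tibble::as_tibble(run$fits$male), "fit_edges_male.tsv")
  w(tibble::as_tibble(run$dmi), "delta_mi.tsv")
  w(tibble::as_tibble(run$d_fc14), "delta_fc14.tsv")
  w(tibble::as_tibble(run$d_slope), "delta_slope.tsv")
  w(run$ranking, "pls1_ranking.tsv")
  w(run$enrichment, "module_enrichment.tsv")
  w(run$chromosome_profile, "chromosome_profile.tsv")
  w(run$tmap, "casecontrol_tmap.tsv")
  w(run$colocation, "colocation.tsv")
  jsonlite::write_json(
    list(seed = run$config$seed,
         parameters = run$config[setdiff(names(run$config), "cohort")],
         glance = glance(run)),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(run)), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
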