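#' Configure a synthetic accelerated-longitudinal cohort
#'
#' Defines the study design and generative model for [simulate_cohort()]. The
#' defaults emulate an accelerated longitudinal adolescent neuroimaging study:
#' five age strata spanning 14-26 years with recruitment balanced for sex
#' within each stratum, one to three scans per subject (follow-ups ~6 and ~18
#' months after baseline), three acquisition sites, and slightly higher head
#' motion in males.
#'
#' Edgewise functional connectivity (Fisher-z units) follows a linear
#' developmental trajectory per sex: baseline connectivity at age 14 plus an
#' annual rate of change, a subject-specific random intercept, a site offset,
#' a head-motion (framewise displacement, FD) confound shared equally by all
#' edges, and scan-level noise. Per-node maturational index (the Spearman
#' correlation between a node's edgewise baselines and slopes) is planted per
#' sex via `target_mi_*`.
#'
#' @param n_subjects total subjects across strata.
#' @param age_strata list of `c(low, high)` year bounds for baseline age.
#' @param scans_per_subject named probabilities over 1, 2 and 3 scans.
#' @param n_regions_cortical,n_regions_subcortical atlas sizes (cortical
#'   regions are split half/half over hemispheres).
#' @param n_timepoints time-series length (only used in `mode = "timeseries"`).
#' @param sites number of acquisition sites.
#' @param fd_mean,fd_sd,fd_sex_shift mean FD model (mm); males are shifted by
#'   `fd_sex_shift`.
#' @param fd_outlier_p probability that a scan is a high-motion outlier,
#'   drawn from a shifted FD distribution so that quality control has
#'   realistic exclusions.
#' @param fc14_mean,fc14_sd population distribution of edgewise baseline
#'   connectivity at age 14 (Fisher z).
#' @param fc14_sex_gap additive male-minus-female difference in baseline
#'   connectivity (Fisher z); positive means stronger male connectivity.
#' @param slope_mean,slope_sd population distribution of annual rates of
#'   change (Fisher z / year).
#' @param target_mi_female,target_mi_male per-node maturational-index targets
#'   in \[-1, 1\]; scalars are recycled, vectors must have one value per region.
#' @param subject_sd SD of edge-specific subject random intercepts (Fisher z).
#' @param subject_global_sd SD of a subject offset shared by all edges
#'   (Fisher z); this is what limits the precision of between-subject global
#'   FC comparisons, since edge-specific intercepts average out over edges.
#' @param site_sd SD of per-site edge offsets (Fisher z; forced to 0 with a
#'   single site).
#' @param noise_sd scan-level edge noise SD (Fisher z; in time-series mode the
#'   finite series length supplies the sampling noise instead).
#' @param beta_fd FD confound slope (Fisher z per mm), applied identically to
#'   every edge (distance-free).
#' @param mode `"fc_only"` (emit connectivity directly) or `"timeseries"`
#'   (emit regional time series whose correlation matrix matches the planted
#'   connectivity, projected to the nearest valid correlation matrix).
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   cohorts.
#'
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 298,
                          age_strata = list(c(14, 16), c(16, 18), c(18, 20),
                                            c(20, 22), c(22, 26)),
                          scans_per_subject = c(`1` = 0.36, `2` = 0.56, `3` = 0.08),
                          n_regions_cortical = 60,
                          n_regions_subcortical = 8,
                          n_timepoints = 150,
                          sites = 3,
                          fd_mean = 0.12, fd_sd = 0.03, fd_sex_shift = 0.02,
                          fd_outlier_p = 0.05,
                          fc14_mean = 0.25, fc14_sd = 0.15,
                          fc14_sex_gap = 0.03,
                          slope_mean = 0.005, slope_sd = 0.01,
                          target_mi_female = NULL,
                          target_mi_male = NULL,
                          subject_sd = 0.08,
                          subject_global_sd = 0.05,
                          site_sd = 0.02,
                          noise_sd = 0.1,
                          beta_fd = 0.3,
                          mode = c("fc_only", "timeseries"),
                          seed = 1L) {
  mode <- match.arg(mode)
  n_regions <- n_regions_cortical + n_regions_subcortical
  if (n_regions < 3) stop_maturind("need at least 3 regions in total")
  for (s in age_strata) {
    if (s[1] < 14 || s[2] > 26 || s[1] >= s[2]) {
      stop_maturind("age strata must be increasing intervals within [14, 26]")
    }
  }
  if (n_subjects < 2 * length(age_strata)) {
    stop_maturind("cannot sex-balance %d subjects over %d strata",
                  n_subjects, length(age_strata))
  }
  scans_per_subject <- scans_per_subject / sum(scans_per_subject)
  # Default maturational topography: a graded map from disruptive (-0.4) to
  # conservative (+0.4), identical in the two sexes (no planted sex difference).
  default_mi <- seq(-0.4, 0.4, length.out = n_regions)
  expand_mi <- function(x, what) {
    x <- x %||% default_mi
    if (length(x) == 1) x <- rep(x, n_regions)
    if (length(x) != n_regions) {
      stop_maturind("%s must have length 1 or %d", what, n_regions)
    }
    if (any(abs(x) > 1)) stop_maturind("%s must lie in [-1, 1]", what)
    x
  }
  structure(list(
    n_subjects = n_subjects, age_strata = age_strata,
    scans_per_subject = scans_per_subject,
    n_regions_cortical = n_regions_cortical,
    n_regions_subcortical = n_regions_subcortical,
    n_timepoints = n_timepoints, sites = sites,
    fd_mean = fd_mean, fd_sd = fd_sd, fd_sex_shift = fd_sex_shift,
    fd_outlier_p = fd_outlier_p,
    fc14_mean = fc14_mean, fc14_sd = fc14_sd, fc14_sex_gap = fc14_sex_gap,
    slope_mean = slope_mean, slope_sd = slope_sd,
    target_mi_female = expand_mi(target_mi_female, "target_mi_female"),
    target_mi_male = expand_mi(target_mi_male, "target_mi_male"),
    subject_sd = subject_sd, subject_global_sd = subject_global_sd,
    site_sd = if (sites > 1) site_sd else 0,
    noise_sd = noise_sd, beta_fd = beta_fd,
    mode = mode, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Region labels of a synthetic atlas
#'
#' Cortical labels are split half/half over left/right hemispheres; the
#' remainder are subcortical.
#'
#' @param n_cortical,n_subcortical atlas sizes.
#' @return A tibble with columns `region`, `kind`, `hemisphere`.
#' @export
synthetic_atlas <- function(n_cortical, n_subcortical = 0) {
  n_left <- ceiling(n_cortical / 2)
  ctx <- c(sprintf("ctx_L_%03d", seq_len(n_left)),
           sprintf("ctx_R_%03d", seq_len(n_cortical - n_left)))
  sub <- if (n_subcortical > 0) sprintf("sub_%03d", seq_len(n_subcortical)) else character(0)
  tibble::tibble(
    region = c(ctx, sub),
    kind = rep(c("cortical", "subcortical"), c(n_cortical, n_subcortical)),
    hemisphere = c(rep(c("L", "R"), c(n_left, n_cortical - n_left)),
                   rep(NA_character_, n_subcortical))
  )
}

#' Draw the cohort design (metadata only)
#'
#' Subjects are allocated to age strata as evenly as possible and sex-balanced
#' within each stratum (counts differ by at most one). Baseline ages are
#' uniform within the stratum, constrained so follow-up scans (+0.5 and +1.5
#' years) stay within 14-26; mean FD is drawn per scan with a male shift.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per scan: `scan_id`, `subject_id`, `sex`,
#'   `age`, `stratum`, `site`, `mean_fd`, `max_fd`, `icv`.
#' @export
simulate_design <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n_strata <- length(config$age_strata)
  per_stratum <- rep(config$n_subjects %/% n_strata, n_strata)
  extra <- config$n_subjects %% n_strata
  if (extra > 0) per_stratum[seq_len(extra)] <- per_stratum[seq_len(extra)] + 1
  subjects <- purrr::map_dfr(seq_len(n_strata), function(k) {
    n_k <- per_stratum[k]
    n_f <- ceiling(n_k / 2)
    if (k %% 2 == 0) n_f <- n_k - n_f  # alternate which sex takes the odd subject
    lo <- config$age_strata[[k]][1]
    hi <- min(config$age_strata[[k]][2], 26 - 1.5)
    tibble::tibble(
      stratum = k,
      sex = sample(rep(c("female", "male"), c(n_f, n_k - n_f))),
      age0 = runif(n_k, lo, hi),
      n_scans = sample(as.integer(names(config$scans_per_subject)), n_k,
                       replace = TRUE, prob = config$scans_per_subject),
      site = sample.int(config$sites, n_k, replace = TRUE)
    )
  })
  subjects$subject_id <- sprintf("sub%04d", seq_len(nrow(subjects)))
  meta <- subjects |>
    dplyr::rowwise() |>
    dplyr::mutate(visit = list(seq_len(.data$n_scans))) |>
    tidyr::unnest("visit") |>
    dplyr::ungroup() |>
    dplyr::mutate(
      age = .data$age0 + c(0, 0.5, 1.5)[.data$visit],
      scan_id = sprintf("%s_v%d", .data$subject_id, .data$visit)
    )
  n <- nrow(meta)
  meta$mean_fd <- pmax(0.01, rnorm(n, config$fd_mean +
                                     config$fd_sex_shift * (meta$sex == "male"),
                                   config$fd_sd))
  outlier <- runif(n) < config$fd_outlier_p
  meta$mean_fd[outlier] <- pmax(0.05, rnorm(sum(outlier), 0.35, 0.08))
  meta$max_fd <- meta$mean_fd * runif(n, 2, 6)
  meta$icv <- rnorm(n, 1.45e6 + 1e5 * (meta$sex == "male"), 8e4)
  # ICV is a subject-level trait: keep the baseline draw for all visits
  meta <- meta |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(icv = .data$icv[1]) |>
    dplyr::ungroup()
  meta |>
    dplyr::select("scan_id", "subject_id", "sex", "age", "stratum", "site",
                  "mean_fd", "max_fd", "icv")
}

# Pearson correlation whose bivariate-normal Spearman correlation equals rho_s.
pearson_for_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Solve per-node edge loadings so that each node's expected edgewise
# correlation between baseline and slope equals its target. Every edge is
# shared by two nodes, so loadings are coupled; a damped fixed point on the
# node coefficients c solves (c_i + mean_{j~i} c_j)/2 = r_i * sd_i(slope).
plant_slopes <- function(z_fc14, edges_idx, n_regions, target_mi,
                         slope_mean, slope_sd, eps) {
  r_target <- pearson_for_spearman(target_mi)
  ia <- edges_idx[, 1]; ib <- edges_idx[, 2]
  deg <- tabulate(ia, n_regions) + tabulate(ib, n_regions)
  node_mean <- function(x_edge) {
    (rowsum_vec(x_edge, ia, n_regions) + rowsum_vec(x_edge, ib, n_regions)) / deg
  }
  c_vec <- 2 * r_target * slope_sd
  for (it in 1:60) {
    g <- (c_vec[ia] + c_vec[ib]) / 2
    tau2 <- max(slope_sd^2 - mean(g^2), 1e-12)
    s_node <- sqrt(node_mean(g^2) + tau2)
    neigh <- 2 * node_mean(c_vec[ia] + c_vec[ib]) / 2 - c_vec  # mean of partner coefs
    c_new <- 2 * r_target * s_node - neigh
    c_vec <- 0.5 * c_vec + 0.5 * c_new
  }
  g <- (c_vec[ia] + c_vec[ib]) / 2
  tau <- sqrt(max(slope_sd^2 - mean(g^2), 1e-12))
  slope_mean + g * z_fc14 + tau * eps
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Edge-level generative truth for both sexes. The baseline map is shared (an
# additive male shift), mirroring the consistent male > female baseline
# difference, while slope noise is drawn independently per sex so that the
# per-sex planted maturational indices are independent samples around their
# targets (required for calibrated null inference on their difference).
plant_edge_truth <- function(config, atlas) {
  n_regions <- nrow(atlas)
  et <- edge_table(atlas$region)
  idx <- cbind(match(et$region_a, atlas$region), match(et$region_b, atlas$region))
  n_edges <- nrow(et)
  fc14_f <- rnorm(n_edges, config$fc14_mean, config$fc14_sd)
  fc14_m <- fc14_f + config$fc14_sex_gap
  z <- as.vector(scale(fc14_f))
  slope_f <- plant_slopes(z, idx, n_regions, config$target_mi_female,
                          config$slope_mean, config$slope_sd, rnorm(n_edges))
  slope_m <- plant_slopes(z, idx, n_regions, config$target_mi_male,
                          config$slope_mean, config$slope_sd, rnorm(n_edges))
  list(edges = tibble::tibble(
    edge = et$edge, region_a = et$region_a, region_b = et$region_b,
    fc14_female = fc14_f, fc14_male = fc14_m,
    slope_female = slope_f, slope_male = slope_m
  ), idx = idx)
}

node_spearman <- function(et, x, y, regions) {
  vapply(regions, function(r) {
    sel <- et$region_a == r | et$region_b == r
    cor(x[sel], y[sel], method = "spearman")
  }, numeric(1))
}

#' Simulate a synthetic developmental cohort with known ground truth
#'
#' Draws the design via [simulate_design()], plants edgewise developmental
#' trajectories per sex, and emits either per-scan Fisher-z connectivity
#' (`mode = "fc_only"`) or regional time series drawn from a multivariate
#' normal whose correlation matrix matches the planted connectivity projected
#' to the nearest valid correlation matrix (`mode = "timeseries"`,
#' eigenvalue floor 1e-6).
#'
#' The expected Fisher-z connectivity of edge e in a scan of subject s at age
#' a is `fc14_e + slope_e * (a - 14) + u_{s,e} + site_{site(s),e} +
#' beta_fd * (FD_scan - fd_mean)`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{metadata}{scan table from [simulate_design()]}
#'     \item{atlas}{region table from [synthetic_atlas()]}
#'     \item{fc}{an [fc_stack()] (`fc_only` mode) or `NULL`}
#'     \item{timeseries}{named list of regions x timepoints matrices
#'       (`timeseries` mode) or `NULL`}
#'     \item{truth}{planted generative quantities, including per-node target
#'       and empirically planted maturational indices and their sex difference}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  meta <- simulate_design(config)
  atlas <- synthetic_atlas(config$n_regions_cortical, config$n_regions_subcortical)
  set.seed(derive_seed(config$seed, 2L))
  truth_edges <- plant_edge_truth(config, atlas)
  et <- truth_edges$edges
  n_edges <- nrow(et)
  n_scans <- nrow(meta)
  subjects <- unique(meta$subject_id)
  subj_int <- matrix(rnorm(length(subjects) * n_edges, 0, config$subject_sd),
                     length(subjects), n_edges, dimnames = list(subjects, NULL))
  subj_int <- subj_int + rnorm(length(subjects), 0, config$subject_global_sd)
  site_eff <- matrix(rnorm(config$sites * n_edges, 0, config$site_sd),
                     config$sites, n_edges)

  is_male <- meta$sex == "male"
  fc14 <- ifelse(rep(is_male, each = n_edges),
                 rep(et$fc14_male, times = n_scans), rep(et$fc14_female, times = n_scans))
  slope <- ifelse(rep(is_male, each = n_edges),
                  rep(et$slope_male, times = n_scans), rep(et$slope_female, times = n_scans))
  expected <- matrix(fc14 + slope * rep(meta$age - 14, each = n_edges),
                     n_edges, n_scans)
  expected <- expected + t(subj_int[meta$subject_id, , drop = FALSE]) +
    t(site_eff[meta$site, , drop = FALSE]) +
    matrix(config$beta_fd * (meta$mean_fd - config$fd_mean),
           n_edges, n_scans, byrow = TRUE)

  truth <- structure(list(
    config = config,
    edges = et,
    nodes = tibble::tibble(
      region = atlas$region,
      target_mi_female = config$target_mi_female,
      target_mi_male = config$target_mi_male,
      planted_mi_female = node_spearman(et, et$fc14_female, et$slope_female, atlas$region),
      planted_mi_male = node_spearman(et, et$fc14_male, et$slope_male, atlas$region),
      delta_mi = config$target_mi_female - config$target_mi_male
    ),
    subject_sd = config$subject_sd, noise_sd = config$noise_sd,
    beta_fd = config$beta_fd, seed = config$seed
  ), class = "synthetic_truth")

  out <- list(metadata = meta, atlas = atlas, fc = NULL, timeseries = NULL,
              truth = truth)
  if (config$mode == "fc_only") {
    vals <- t(expected + matrix(rnorm(n_edges * n_scans, 0, config$noise_sd),
                                n_edges, n_scans))
    out$fc <- fc_stack(vals, atlas$region, meta$scan_id)
  } else {
    out$timeseries <- purrr::map(seq_len(n_scans), function(s) {
      r_mat <- edges_to_mat(tanh(expected[, s]), atlas$region)
      diag(r_mat) <- 1
      r_proj <- nearest_correlation(r_mat, floor = 1e-6)
      ch <- tryCatch(chol(r_proj), error = function(e) NULL)
      if (is.null(ch)) {
        stop_maturind("correlation projection failed for scan %s", meta$scan_id[s])
      }
      ts <- t(ch) %*% matrix(rnorm(nrow(r_mat) * config$n_timepoints),
                             nrow(r_mat), config$n_timepoints)
      rownames(ts) <- atlas$region
      ts
    })
    names(out$timeseries) <- meta$scan_id
  }
  structure(out, class = "synthetic_cohort")
}

# Nearest correlation matrix via eigenvalue flooring + diagonal rescaling.
nearest_correlation <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d scans / %d subjects, %d regions (%s mode)\n",
              nrow(x$metadata), length(unique(x$metadata$subject_id)),
              nrow(x$atlas), x$truth$config$mode))
  invisible(x)
}

#' Simulate a regional gene-expression panel with a planted module
#'
#' Generates a cortical regions x genes expression matrix in which a module of
#' genes is expressed in (anti-)correlation with a target regional map:
#' each module gene's expected correlation with the target is `-rho`, so with
#' `rho > 0` the module lands at the negative-weight end of the first partial
#' least squares component of the target on expression. Background genes are
#' independent noise. Gene annotations (chromosome, length) are drawn from a
#' declared long-tailed model: chromosome labels with frequencies proportional
#' to approximate human protein-coding gene counts (including X and Y) and
#' log-normal gene lengths.
#'
#' @param target_map regional map (named vector or tibble `region`, `value`)
#'   over cortical regions.
#' @param n_genes,module_size panel size and planted-module size.
#' @param rho absolute expected correlation between module-gene expression and
#'   the target, in \[0, 1\].
#' @param x_frac_module probability that a module gene is assigned to the X
#'   chromosome (0 = same chromosome model as background; raise to plant
#'   X-linked enrichment).
#' @param seed integer seed.
#' @return A list with `expression` (regions x genes matrix), `genes` (tibble
#'   `gene`, `chromosome`, `length`, `in_module`).
#' @export
simulate_expression_panel <- function(target_map, n_genes = 2000,
                                      module_size = 100, rho = 0.9,
                                      x_frac_module = 0, seed = 1L) {
  tm <- as_regional_map(target_map)
  if (sd(tm$value) == 0) stop_maturind("target map has zero variance")
  if (rho < 0 || rho > 1) stop_maturind("rho must lie in [0, 1]")
  if (module_size >= n_genes) stop_maturind("module_size must be < n_genes")
  set.seed(as.integer(seed))
  n_r <- nrow(tm)
  t_z <- as.vector(scale(tm$value))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  in_module <- seq_len(n_genes) <= module_size
  expr <- matrix(rnorm(n_r * n_genes), n_r, n_genes,
                 dimnames = list(tm$region, genes))
  expr[, in_module] <- -(rho * t_z + sqrt(1 - rho^2) * expr[, in_module])
  # Approximate protein-coding gene counts per chromosome (1-22, X, Y).
  chrom_levels <- c(as.character(1:22), "X", "Y")
  chrom_weights <- c(2000, 1300, 1100, 800, 900, 1050, 950, 700, 800, 750,
                     1300, 1050, 350, 650, 600, 850, 1200, 300, 1450, 550,
                     250, 450, 850, 70)
  chrom <- sample(chrom_levels, n_genes, replace = TRUE,
                  prob = chrom_weights / sum(chrom_weights))
  if (x_frac_module > 0) {
    flip <- in_module & runif(n_genes) < x_frac_module
    chrom[flip] <- "X"
  }
  gene_table <- tibble::tibble(
    gene = genes,
    chromosome = chrom,
    length = round(exp(rnorm(n_genes, log(2e4), 1.1))),
    in_module = in_module
  )
  list(expression = expr, genes = gene_table)
}

#' Simulate unit-sphere coordinates for a cortical atlas
#'
#' Region centroids on the unit sphere, split into left/right hemispheres by
#' the sign of the x axis; right-hemisphere points mirror left-hemisphere
#' points so that homologous pairs correspond. Labels match
#' [synthetic_atlas()].
#'
#' @param n_cortical number of cortical regions (>= 3).
#' @param seed integer seed.
#' @return A tibble `region`, `hemisphere`, `x`, `y`, `z`.
#' @export
simulate_sphere_coords <- function(n_cortical, seed = 1L) {
  if (n_cortical < 3) stop_maturind("need at least 3 cortical regions")
  set.seed(as.integer(seed))
  n_left <- ceiling(n_cortical / 2)
  n_right <- n_cortical - n_left
  pts <- matrix(rnorm(3 * n_left), n_left, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  pts[, 1] <- -abs(pts[, 1])
  right <- pts[seq_len(n_right), , drop = FALSE]
  right[, 1] <- -right[, 1]
  atlas <- synthetic_atlas(n_cortical, 0)
  tibble::tibble(
    region = atlas$region,
    hemisphere = atlas$hemisphere,
    x = c(pts[, 1], right[, 1]),
    y = c(pts[, 2], right[, 2]),
    z = c(pts[, 3], right[, 3])
  )
}

#' Simulate case-control nodal degree maps with a planted colocation
#'
#' Constructs per-subject weighted-degree maps for a case and a control group
#' whose expected case-minus-control difference is an affine function of a
#' target map, scaled so the spatial correlation between the expected
#' difference map and the target is exactly `r_target` (the target is mixed
#' with an orthogonalised noise map).
#'
#' @param target_map regional map the group difference should colocate with.
#' @param effect SD (over regions) of the expected case-control degree
#'   difference, Fisher-z units.
#' @param r_target desired spatial correlation in \[-1, 1\].
#' @param n_cases,n_controls group sizes (>= 2 each).
#' @param subject_sd between-subject degree SD within group.
#' @param seed integer seed.
#' @return A list: `degrees` (subjects x regions matrix), `labels` (tibble
#'   `subject`, `group`), `truth` (planted difference map and `r_target`).
#' @export
simulate_casecontrol <- function(target_map, effect = 1, r_target = 0.4,
                                 n_cases = 50, n_controls = 46,
                                 subject_sd = 1, seed = 1L) {
  tm <- as_regional_map(target_map)
  if (abs(r_target) > 1) stop_maturind("r_target must lie in [-1, 1]")
  if (n_cases < 2 || n_controls < 2) stop_maturind("need at least 2 subjects per group")
  if (sd(tm$value) == 0) stop_maturind("target map has zero variance")
  set.seed(as.integer(seed))
  n_r <- nrow(tm)
  z <- as.vector(scale(tm$value))
  if (abs(r_target) < 1) {
    w <- rnorm(n_r)
    w_perp <- as.vector(scale(stats::residuals(lm(w ~ z))))
    m <- r_target * z + sqrt(1 - r_target^2) * w_perp
  } else {
    m <- sign(r_target) * z
  }
  d <- effect * m
  baseline <- rnorm(n_r, 0.5, 0.1)
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  deg <- matrix(rnorm(n * n_r, 0, subject_sd), n, n_r, byrow = FALSE)
  deg <- sweep(deg, 2, baseline, `+`)
  deg[group == "case", ] <- sweep(deg[group == "case", , drop = FALSE], 2, d, `+`)
  subjects <- sprintf("cc%03d", seq_len(n))
  dimnames(deg) <- list(subjects, tm$region)
  list(
    degrees = deg,
    labels = tibble::tibble(subject = subjects, group = group),
    truth = list(diff_map = setNames(d, tm$region), r_target = r_target,
                 effect = effect, seed = as.integer(seed))
  )
}
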