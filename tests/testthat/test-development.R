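test_that("ols and lme engines agree when every subject has one scan", {
  cfg <- cohort_config(n_subjects = 40, n_regions_cortical = 6,
                       n_regions_subcortical = 0,
                       scans_per_subject = c(`1` = 1, `2` = 0, `3` = 0),
                       seed = 12)
  co <- simulate_cohort(cfg)
  ols <- fit_trajectories(co$fc, co$metadata, "female", engine = "ols")
  lme <- fit_trajectories(co$fc, co$metadata, "female", engine = "lme")
  expect_lt(max(abs(ols$fc14 - lme$fc14)), 1e-6)
  expect_lt(max(abs(ols$slope - lme$slope)), 1e-6)
})

test_that("lme engine recovers a planted slope at the node level", {
  cfg <- cohort_config(n_subjects = 60, n_regions_cortical = 8,
                       n_regions_subcortical = 0, noise_sd = 0.03,
                       subject_sd = 0.02, subject_global_sd = 0.01,
                       beta_fd = 0, seed = 13)
  co <- simulate_cohort(cfg)
  deg <- stack_degrees(co$fc)
  fit <- fit_trajectories(deg, co$metadata, "male", unit = "node", engine = "lme")
  # planted nodal slope = mean incident edge slope
  et <- co$truth$edges
  planted <- vapply(co$atlas$region, function(r) {
    sel <- et$region_a == r | et$region_b == r
    mean(et$slope_male[sel])
  }, numeric(1))
  expect_lt(max(abs(fit$slope - unname(planted))), 0.01)
  expect_true(all(fit$se_fc14 > 0) && all(fit$se_slope > 0))
  expect_true(all(fit$n_obs >= fit$n_subjects))
})

test_that("trajectory fitting validates its inputs", {
  co <- simulate_cohort(cohort_config(n_subjects = 12, n_regions_cortical = 6,
                                      n_regions_subcortical = 0, seed = 1))
  meta_small <- co$metadata[co$metadata$subject_id %in%
                              unique(co$metadata$subject_id)[1:2], ]
  expect_error(fit_trajectories(co$fc, meta_small, "female"), "3 subjects")
  expect_error(fit_trajectories(co$fc, co$metadata, "other"), "sex")
})

test_that("maturational index matches hand cases and the rank-Pearson oracle", {
  mk_fit <- function(fc14, slope) {
    n <- length(fc14)
    tb <- tibble::tibble(
      unit = sprintf("hub|r%02d", seq_len(n)),
      region_a = "hub", region_b = sprintf("r%02d", seq_len(n)),
      fc14 = fc14, slope = slope,
      se_fc14 = 0.01, se_slope = 0.001, n_obs = 50, n_subjects = 25,
      sex = "female"
    )
    structure(tb, class = c("dev_fit", class(tb)),
              sex = "female", unit = "edge", engine = "ols")
  }
  # perfect monotone association
  hi <- maturational_index(mk_fit(c(1, 2, 3, 4), c(2, 4, 6, 8)), regions = "hub")
  expect_equal(hi$mi[hi$region == "hub"], 1)
  lo <- maturational_index(mk_fit(c(1, 2, 3, 4), c(-1, -2, -3, -4)), regions = "hub")
  expect_equal(lo$mi[lo$region == "hub"], -1)
  # oracle equivalence on random 20-edge nodes
  set.seed(21)
  for (rep in 1:10) {
    fc14 <- rnorm(20); slope <- 0.3 * fc14 + rnorm(20)
    mi <- maturational_index(mk_fit(fc14, slope), regions = "hub")
    expect_equal(mi$mi[mi$region == "hub"], spearman_oracle(fc14, slope),
                 tolerance = 1e-12)
    n <- 20
    expect_equal(mi$se_mi[mi$region == "hub"],
                 sqrt((1 - spearman_oracle(fc14, slope)^2) / (n - 2)),
                 tolerance = 1e-12)
  }
  # degenerate ranks
  expect_error(maturational_index(mk_fit(rep(1, 5), rnorm(5)), regions = "hub"),
               "constant fc14")
})

test_that("sex-difference Z statistics evaluate their defining formulas", {
  mk_mi <- function(mi, se, sex) {
    tb <- tibble::tibble(region = sprintf("n%02d", seq_along(mi)),
                         mi = mi, se_mi = se, n_edges = 20, sex = sex)
    structure(tb, class = c("mi_result", class(tb)), sex = sex)
  }
  d <- delta_mi(mk_mi(0.3, 0.1, "female"), mk_mi(-0.1, 0.1, "male"))
  expect_equal(d$z, (0.3 - (-0.1)) / sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(d$z, 2.8284, tolerance = 1e-4)
  expect_equal(d$p, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)
  # null and antisymmetry
  null <- delta_mi(mk_mi(0.2, 0.05, "female"), mk_mi(0.2, 0.05, "male"))
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)
  set.seed(2)
  f <- mk_mi(runif(30, -0.5, 0.5), runif(30, 0.05, 0.2), "female")
  m <- mk_mi(runif(30, -0.5, 0.5), runif(30, 0.05, 0.2), "male")
  expect_equal(delta_mi(f, m)$z, -delta_mi(m, f)$z, tolerance = 1e-12)
  expect_error(delta_mi(f, mk_mi(runif(5), 0.1, "male")), "node sets")
})

test_that("parameter differences combine regression SEs in quadrature", {
  mk_fit <- function(theta, se, sex) {
    tb <- tibble::tibble(unit = sprintf("u%03d", seq_along(theta)),
                         fc14 = theta, slope = theta / 10,
                         se_fc14 = se, se_slope = se / 10,
                         n_obs = 100, n_subjects = 60, sex = sex)
    structure(tb, class = c("dev_fit", class(tb)),
              sex = sex, unit = "edge", engine = "ols")
  }
  d <- delta_param(mk_fit(0.5, 0.05, "female"), mk_fit(0.3, 0.05, "male"), "fc14")
  expect_equal(d$z, (0.5 - 0.3) / sqrt(2 * 0.05^2), tolerance = 1e-12)
  expect_equal(d$z, 2.8284, tolerance = 1e-4)
  same <- delta_param(mk_fit(0.4, 0.1, "female"), mk_fit(0.4, 0.1, "male"), "slope")
  expect_equal(same$z, 0)
  set.seed(3)
  f <- mk_fit(rnorm(50), runif(50, 0.01, 0.1), "female")
  m <- mk_fit(rnorm(50), runif(50, 0.01, 0.1), "male")
  expect_equal(delta_param(f, m, "slope")$z, -delta_param(m, f, "slope")$z,
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the hand-applied step-up", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$significant))
  expect_true(all(r$q >= r$p))
  none <- fdr_bh(rep(1, 10))
  expect_false(any(none$significant))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # significance is monotone in p
  set.seed(4)
  p <- runif(100, 0, 0.2)
  rr <- fdr_bh(p)
  if (any(rr$significant) && any(!rr$significant)) {
    expect_lt(max(p[rr$significant]), min(p[!rr$significant]) + 1e-15)
  }
})

test_that("developmental-mode classification follows the sign rules", {
  d <- tibble::tibble(
    unit = c("a", "b", "c", "d", "e"),
    female = c(-0.3, 0.2, 0.2, 0.6, -0.5),
    male = c(0.1, 0.5, -0.1, 0.2, 0.3),
    delta = c(-0.4, -0.3, 0.3, 0.4, -0.8),
    z = c(-3, -3, 3, 3, -1), p = c(0.001, 0.001, 0.001, 0.001, 0.3),
    q = c(0.01, 0.01, 0.01, 0.01, 0.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- classify_development(d)
  expect_equal(out$mode,
               c("female_more_disruptive", "female_less_conservative",
                 "male_more_disruptive", "male_less_conservative",
                 "no_difference"))
})

test_that("global FC model recovers a planted sex offset and is label-antisymmetric", {
  cfg <- cohort_config(n_subjects = 120, n_regions_cortical = 20,
                       n_regions_subcortical = 0, fc14_sex_gap = 0.05,
                       subject_global_sd = 0.03, seed = 31)
  co <- simulate_cohort(cfg)
  g <- global_fc(co$fc)
  fit <- global_fc_model(g, co$metadata)
  t_sex <- fit$statistic[fit$term == "sexmale"]
  expect_gt(t_sex, 2)  # male > female planted
  # swapping sex labels negates the sex coefficient exactly
  meta_swap <- dplyr::mutate(co$metadata,
                             sex = ifelse(sex == "male", "female", "male"))
  fit_swap <- global_fc_model(g, meta_swap)
  expect_equal(fit_swap$estimate[fit_swap$term == "sexmale"],
               -fit$estimate[fit$term == "sexmale"], tolerance = 1e-8)
  expect_error(global_fc_model(g, dplyr::mutate(co$metadata, sex = "female")),
               "both sexes")
})

test_that("nodal delta-MI p values are uniform under the null generator", {
  # identical per-sex parameters: pooled p values across replicates should be
  # approximately uniform
  ps <- unlist(lapply(1:8, function(k) {
    cfg <- cohort_config(n_subjects = 80, n_regions_cortical = 24,
                         n_regions_subcortical = 0, fc14_sex_gap = 0,
                         beta_fd = 0, fd_sex_shift = 0, seed = 100 + k)
    co <- simulate_cohort(cfg)
    ff <- fit_trajectories(co$fc, co$metadata, "female")
    fm <- fit_trajectories(co$fc, co$metadata, "male")
    delta_mi(maturational_index(ff), maturational_index(fm))$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
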