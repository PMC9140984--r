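# Per-sex developmental modelling: linear age trajectories of edgewise or
# nodal connectivity with age centred at 14 (so the intercept IS the baseline
# connectivity at 14), fixed site effects, and a subject random intercept
# (lme engine) or subject-clustered OLS (ols engine, the fast default for
# edgewise fits).

build_design <- function(meta) {
  age_c <- meta$age - 14
  x <- cbind(`(Intercept)` = 1, age_c = age_c)
  site <- factor(meta$site)
  if (nlevels(site) > 1) {
    sm <- stats::model.matrix(~site)[, -1, drop = FALSE]
    x <- cbind(x, sm)
  }
  if (qr(x)$rank < ncol(x)) {
    stop_maturind("singular design (site collinear with age?)")
  }
  x
}

# Vectorised OLS over many response columns with CR1 subject-clustered SEs.
ols_fit_many <- function(x, y, subject) {
  qr_x <- qr(x)
  beta <- qr.coef(qr_x, y)
  resid <- y - x %*% beta
  k <- ncol(x)
  n <- nrow(x)
  xtx_inv <- chol2inv(qr.R(qr_x))
  g <- length(unique(subject))
  # Meat of the sandwich: sum over subjects of (X_g' e_g)(X_g' e_g)'
  u <- lapply(seq_len(k), function(j) rowsum(resid * x[, j], subject))
  cr1 <- (g / (g - 1)) * ((n - 1) / (n - k))
  var_of <- function(j) {
    v <- numeric(ncol(y))
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (xtx_inv[j, a] != 0 && xtx_inv[j, b] != 0) {
          v <- v + xtx_inv[j, a] * xtx_inv[j, b] * colSums(u[[a]] * u[[b]])
        }
      }
    }
    pmax(cr1 * v, 0)
  }
  list(
    fc14 = beta[1, ], slope = beta[2, ],
    se_fc14 = sqrt(var_of(1)), se_slope = sqrt(var_of(2))
  )
}

lme_fit_many <- function(meta, y) {
  site <- factor(meta$site)
  has_site <- nlevels(site) > 1
  df <- data.frame(age_c = meta$age - 14, site = site, subject = meta$subject_id)
  fits <- apply(y, 2, function(col) {
    df$y <- col
    form <- if (has_site) y ~ age_c + site + (1 | subject) else y ~ age_c + (1 | subject)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.rankZ = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))
    ))
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    c(b[["(Intercept)"]], b[["age_c"]], se[1], se[2])
  })
  list(fc14 = fits[1, ], slope = fits[2, ], se_fc14 = fits[3, ], se_slope = fits[4, ])
}

#' Fit per-sex linear developmental trajectories
#'
#' For each unit (edge or node), fits `value = fc14 + slope * (age - 14) +
#' site + subject`, returning the predicted connectivity at age 14 (`fc14`,
#' the intercept) and the annual rate of change (`slope`). The `lme` engine
#' fits a linear mixed-effects model with a subject random intercept
#' (lme4); the `ols` engine drops the random intercept and reports
#' subject-clustered (CR1) standard errors — the fast default for edgewise
#' fits, agreeing with `lme` in expectation and exactly when every subject
#' contributes a single scan.
#'
#' @param stack an [fc_stack()] (for `unit = "edge"`) — or, for
#'   `unit = "node"`, either an `fc_stack` (degrees are computed) or a
#'   scans x regions degree matrix.
#' @param metadata scan table (must cover the stack's scans; only scans of
#'   `sex` are used).
#' @param sex `"female"` or `"male"`; trajectories are fit separately per sex.
#' @param unit `"edge"` or `"node"`.
#' @param engine `"ols"` (default) or `"lme"`.
#' @return A `dev_fit` tibble: `unit`, (`region_a`, `region_b` for edges),
#'   `fc14`, `slope`, `se_fc14`, `se_slope`, `n_obs`, `n_subjects`, `sex`,
#'   with attributes `sex`, `unit`, `engine`.
#' @export
fit_trajectories <- function(stack, metadata, sex, unit = c("edge", "node"),
                             engine = c("ols", "lme")) {
  unit <- match.arg(unit)
  engine <- match.arg(engine)
  if (!sex %in% c("female", "male")) stop_maturind("sex must be 'female' or 'male'")
  meta <- dplyr::filter(metadata, .data$sex == !!sex)
  if (length(unique(meta$subject_id)) < 3) stop_maturind("fewer than 3 subjects")
  if (length(unique(meta$age)) < 2) stop_maturind("need at least 2 distinct ages")
  if (inherits(stack, "fc_stack")) {
    y_full <- if (unit == "edge") stack$values else stack_degrees(stack)
  } else {
    if (unit == "edge") stop_maturind("edge fits require an fc_stack")
    y_full <- stack
  }
  missing <- setdiff(meta$scan_id, rownames(y_full))
  if (length(missing) > 0) {
    stop_maturind("scans missing from stack: %s", paste(head(missing, 5), collapse = ", "))
  }
  y <- y_full[meta$scan_id, , drop = FALSE]
  est <- if (engine == "ols") {
    ols_fit_many(build_design(meta), y, meta$subject_id)
  } else {
    build_design(meta)  # validates the fixed-effect design
    lme_fit_many(meta, y)
  }
  out <- tibble::tibble(
    unit = colnames(y),
    fc14 = unname(est$fc14), slope = unname(est$slope),
    se_fc14 = unname(est$se_fc14), se_slope = unname(est$se_slope),
    n_obs = nrow(y), n_subjects = length(unique(meta$subject_id)),
    sex = sex
  )
  if (unit == "edge" && inherits(stack, "fc_stack")) {
    out <- dplyr::left_join(out, stack$edges, by = c(unit = "edge")) |>
      dplyr::relocate("region_a", "region_b", .after = "unit")
  }
  structure(out, class = c("dev_fit", class(out)),
            sex = sex, unit = unit, engine = engine)
}

#' Model age and sex effects on global FC
#'
#' A single linear mixed-effects model of per-scan global FC (mean weighted
#' degree) on age (centred at 14), sex and site, with a subject random
#' intercept. The sex coefficient is the male-minus-female offset.
#'
#' @param global per-scan global FC: tibble `scan_id`, `global_fc` (see
#'   [global_fc()]).
#' @param metadata scan table covering both sexes.
#' @return A tibble `term`, `estimate`, `se`, `statistic` (signed t).
#' @export
global_fc_model <- function(global, metadata) {
  df <- dplyr::inner_join(metadata, global, by = "scan_id")
  if (length(unique(df$sex)) < 2) stop_maturind("both sexes must be present")
  df$age_c <- df$age - 14
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$site <- factor(df$site)
  form <- if (nlevels(df$site) > 1) {
    global_fc ~ age_c + sex + site + (1 | subject_id)
  } else {
    global_fc ~ age_c + sex + (1 | subject_id)
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tibble::tibble(term = names(b), estimate = unname(b), se = unname(se),
                 statistic = unname(b) / unname(se))
}

#' Maturational index: per-node Spearman correlation of baseline and change
#'
#' For each node, the Spearman correlation (average ranks under ties) across
#' its incident edges between baseline connectivity at 14 and the annual rate
#' of change. Positive values indicate conservative development (strong
#' connections get stronger), negative values disruptive development (weak
#' connections get stronger and/or strong get weaker).
#'
#' The default standard error is the classical large-sample form
#' `sqrt((1 - mi^2)/(n_edges - 2))`; `se_method = "fisher"` instead
#' delta-transforms the Fisher-z standard error `sqrt(1.06/(n - 3))`.
#'
#' @param fit an edge-level `dev_fit` from [fit_trajectories()].
#' @param se_method `"classic"` (default) or `"fisher"`.
#' @param regions optional subset of nodes to compute (default: every node
#'   appearing in the fit).
#' @return An `mi_result` tibble: `region`, `mi`, `se_mi`, `n_edges`, `sex`.
#' @export
maturational_index <- function(fit, se_method = c("classic", "fisher"),
                               regions = NULL) {
  se_method <- match.arg(se_method)
  if (!inherits(fit, "dev_fit") || attr(fit, "unit") != "edge") {
    stop_maturind("maturational_index requires an edge-level dev_fit")
  }
  regions <- regions %||% sort(unique(c(fit$region_a, fit$region_b)))
  rows <- purrr::map_dfr(regions, function(r) {
    sel <- fit$region_a == r | fit$region_b == r
    n <- sum(sel)
    if (n < 4) stop_maturind("node %s has fewer than 4 incident edges", r)
    x <- fit$fc14[sel]
    if (sd(x) == 0) stop_maturind("constant fc14 at node %s: ranks degenerate", r)
    mi <- cor(x, fit$slope[sel], method = "spearman")
    se <- if (se_method == "classic") {
      sqrt((1 - mi^2) / (n - 2))
    } else {
      (1 - mi^2) * sqrt(1.06 / (n - 3))
    }
    tibble::tibble(region = r, mi = mi, se_mi = se, n_edges = n)
  })
  rows$sex <- attr(fit, "sex")
  structure(rows, class = c("mi_result", class(rows)), sex = attr(fit, "sex"))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q values with significance flags at `q_level`.
#'
#' @param p p values in \[0, 1\].
#' @param q_level FDR threshold (default 0.05).
#' @return A tibble `p`, `q`, `significant`.
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  check_probability(p)
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = q <= q_level)
}

delta_table <- function(unit, value_f, value_m, se_f, se_m, q_level,
                        extra = NULL) {
  z <- (value_f - value_m) / sqrt(se_f^2 + se_m^2)
  p <- 2 * pnorm(-abs(z))
  adj <- fdr_bh(p, q_level)
  out <- tibble::tibble(
    unit = unit,
    female = value_f, male = value_m,
    delta = value_f - value_m,
    z = z, p = p, q = adj$q, significant = adj$significant
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(extra, out) |> dplyr::relocate("unit")
  structure(out, class = c("delta_result", class(out)))
}

#' Sex difference in the maturational index
#'
#' Per node, `delta = MI_female - MI_male`, tested by
#' `z = delta / sqrt(SE_female^2 + SE_male^2)` with a two-sided p value from
#' the standard normal and Benjamini-Hochberg FDR adjustment across nodes.
#'
#' @param mi_female,mi_male `mi_result` tibbles over the same node set.
#' @param q_level FDR threshold for the significance flag.
#' @return A `delta_result` tibble: `unit` (region), `female`, `male`,
#'   `delta`, `z`, `p`, `q`, `significant`.
#' @export
delta_mi <- function(mi_female, mi_male, q_level = 0.05) {
  if (!identical(mi_female$region, mi_male$region)) {
    stop_maturind("node sets of the two mi_results do not match")
  }
  delta_table(mi_female$region, mi_female$mi, mi_male$mi,
              mi_female$se_mi, mi_male$se_mi, q_level)
}

#' Sex difference in a developmental regression parameter
#'
#' Per unit (edge or node), the difference between sexes in `fc14` or `slope`
#' divided by the quadrature-combined regression-coefficient standard errors
#' (which already reflect the per-sex numbers of observations):
#' `z = (theta_f - theta_m)/sqrt(SE_f^2 + SE_m^2)`.
#'
#' @param fit_female,fit_male `dev_fit` tibbles over the same units.
#' @param parameter `"fc14"` or `"slope"`.
#' @param q_level FDR threshold for the significance flag.
#' @return A `delta_result` tibble (see [delta_mi()]).
#' @export
delta_param <- function(fit_female, fit_male, parameter = c("fc14", "slope"),
                        q_level = 0.05) {
  parameter <- match.arg(parameter)
  if (!identical(fit_female$unit, fit_male$unit)) {
    stop_maturind("unit sets of the two fits do not match")
  }
  se_col <- paste0("se_", parameter)
  delta_table(fit_female$unit, fit_female[[parameter]], fit_male[[parameter]],
              fit_female[[se_col]], fit_male[[se_col]], q_level)
}

#' Classify nodes by developmental mode of the sex difference
#'
#' FDR-significant nodes with more negative female MI (`delta < 0`) are
#' `female_more_disruptive` when the female MI itself is negative (weak
#' connections getting stronger / strong getting weaker in females) and
#' `female_less_conservative` otherwise; the mirror labels apply for
#' `delta > 0`. Non-significant nodes are `no_difference`.
#'
#' @param delta a `delta_result` from [delta_mi()] (columns `female`, `male`
#'   hold the per-sex MI).
#' @return The input with an added `mode` column.
#' @export
classify_development <- function(delta) {
  delta |>
    dplyr::mutate(mode = dplyr::case_when(
      !.data$significant ~ "no_difference",
      .data$delta < 0 & .data$female < 0 ~ "female_more_disruptive",
      .data$delta < 0 ~ "female_less_conservative",
      .data$delta > 0 & .data$male < 0 ~ "male_more_disruptive",
      .data$delta > 0 ~ "male_less_conservative",
      TRUE ~ "no_difference"
    ))
}

#' @export
glance.dev_fit <- function(x, ...) {
  tibble::tibble(
    sex = attr(x, "sex"), unit = attr(x, "unit"), engine = attr(x, "engine"),
    n_units = nrow(x), n_obs = x$n_obs[1], n_subjects = x$n_subjects[1],
    mean_fc14 = mean(x$fc14), mean_slope = mean(x$slope)
  )
}

#' @export
tidy.dev_fit <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.mi_result <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.delta_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.delta_result <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    n_significant = sum(x$significant),
    n_negative_significant = sum(x$significant & x$delta < 0),
    min_q = min(x$q)
  )
}
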