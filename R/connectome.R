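#' Quality-control scans by head motion
#'
#' A scan is excluded if its mean framewise displacement (FD) exceeds
#' `mean_fd_max` or its maximum FD exceeds `max_fd_max`. Defaults follow the
#' convention of excluding scans with mean FD > 0.3 mm or maximum FD > 1.3 mm.
#'
#' @param metadata scan table with columns `scan_id`, `mean_fd`, `max_fd`.
#' @param mean_fd_max,max_fd_max exclusion thresholds in mm.
#' @return The metadata with added columns `qc_pass` (logical) and `qc_reason`
#'   (`NA` for retained scans; otherwise `"mean_fd"`, `"max_fd"` or both,
#'   semicolon-separated).
#' @export
qc_scans <- function(metadata, mean_fd_max = 0.3, max_fd_max = 1.3) {
  if (!all(c("mean_fd", "max_fd") %in% names(metadata))) {
    stop_maturind("metadata must contain mean_fd and max_fd")
  }
  bad_na <- !is.finite(metadata$mean_fd) | !is.finite(metadata$max_fd)
  if (any(bad_na)) {
    stop_maturind("missing FD for scan(s): %s",
                  paste(head(metadata$scan_id[bad_na], 5), collapse = ", "))
  }
  metadata |>
    dplyr::mutate(
      .mean_bad = .data$mean_fd > mean_fd_max,
      .max_bad = .data$max_fd > max_fd_max,
      qc_pass = !.data$.mean_bad & !.data$.max_bad,
      qc_reason = dplyr::case_when(
        .data$.mean_bad & .data$.max_bad ~ "mean_fd;max_fd",
        .data$.mean_bad ~ "mean_fd",
        .data$.max_bad ~ "max_fd",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(-".mean_bad", -".max_bad")
}

#' Normalise regional time series to zero mean and unit SD
#'
#' @param ts regions x timepoints matrix.
#' @return Matrix of the same shape; each row has mean 0 and SD 1.
#' @export
normalize_timeseries <- function(ts) {
  if (ncol(ts) < 2) stop_maturind("need at least 2 timepoints per region")
  sds <- apply(ts, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(ts)[sds == 0] %||% which(sds == 0)
    stop_maturind("zero-variance region(s): %s", paste(head(bad, 5), collapse = ", "))
  }
  t(scale(t(ts)))[, , drop = FALSE] |>
    (`dimnames<-`)(dimnames(ts))
}

#' Fisher-z functional connectivity matrix from regional time series
#'
#' Pearson correlation of every region pair, Fisher-transformed
#' (`atanh`), so connectivity is in units of SDs of the normal distribution.
#' The diagonal is undefined and set to `NA`.
#'
#' @param ts regions x timepoints matrix (rows named by region).
#' @return Symmetric regions x regions Fisher-z matrix with `NA` diagonal.
#' @export
fc_matrix <- function(ts) {
  r <- cor(t(ts))
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    idx <- which(upper.tri(r), arr.ind = TRUE)[which(off >= 1 - 1e-12)[1], ]
    stop_maturind("degenerate correlation |r| ~ 1 between %s and %s (infinite Fisher z)",
                  rownames(r)[idx[1]], rownames(r)[idx[2]])
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Exclude regions with low mean signal in any scan
#'
#' Regional mean signal intensities are standardised across regions within
#' each scan; a region is dropped if its Z score falls below `z_thresh` in at
#' least one scan.
#'
#' @param signal_means scans x regions matrix of regional mean signal
#'   intensities (columns named by region).
#' @param z_thresh exclusion threshold (default -1.96).
#' @return A tibble with columns `region`, `min_z`, `retained`.
#' @export
exclude_low_signal <- function(signal_means, z_thresh = -1.96) {
  z <- t(apply(signal_means, 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  min_z <- apply(z, 2, min)
  tibble::tibble(
    region = colnames(signal_means) %||% as.character(seq_len(ncol(signal_means))),
    min_z = unname(min_z),
    retained = unname(min_z >= z_thresh)
  )
}

# Shared engine for edgewise confound regression: per edge, OLS residuals of
# the edge values on the covariate, re-centred to the pre-regression mean so
# connectivity keeps its Fisher-z units.
regress_stack <- function(values, covariate, groups = NULL) {
  if (length(covariate) != nrow(values)) {
    stop_maturind("covariate length %d does not match %d scans",
                  length(covariate), nrow(values))
  }
  do_group <- function(rows) {
    x <- covariate[rows]
    if (sd(x) == 0) stop_maturind("covariate is constant within a regression group")
    y <- values[rows, , drop = FALSE]
    xc <- x - mean(x)
    beta <- crossprod(xc, y) / sum(xc^2)
    ybar <- colMeans(y)
    resid <- sweep(y, 2, ybar) - outer(xc, drop(beta))
    sweep(resid, 2, ybar, `+`)
  }
  out <- values
  if (is.null(groups)) {
    out[] <- do_group(seq_len(nrow(values)))
  } else {
    for (g in unique(groups)) {
      rows <- which(groups == g)
      if (length(rows) < 3) stop_maturind("fewer than 3 scans in group '%s'", g)
      out[rows, ] <- do_group(rows)
    }
  }
  out
}

#' Regress head motion out of edgewise connectivity
#'
#' Each edge is regressed on mean FD across scans and replaced by the
#' residuals plus the pre-regression mean (pooled mode) or the group mean
#' (`by_sex` mode, which fits separate regressions per sex and preserves
#' between-sex mean differences).
#'
#' @param stack an [fc_stack()].
#' @param mean_fd per-scan mean FD, aligned with the stack's scans.
#' @param mode `"pooled"` or `"by_sex"`.
#' @param sex per-scan sex labels (required for `by_sex`).
#' @return A motion-corrected `fc_stack` with `fd_regressed = TRUE`.
#' @export
motion_regress <- function(stack, mean_fd, mode = c("pooled", "by_sex"),
                           sex = NULL) {
  mode <- match.arg(mode)
  if (nrow(stack$values) < 3) stop_maturind("need at least 3 scans")
  groups <- NULL
  if (mode == "by_sex") {
    if (is.null(sex)) stop_maturind("by_sex mode requires per-scan sex labels")
    groups <- sex
  }
  out <- stack
  out$values <- regress_stack(stack$values, mean_fd, groups)
  out$provenance$fd_regressed <- TRUE
  out$provenance$fd_mode <- mode
  out
}

#' Regress an arbitrary covariate out of edgewise connectivity
#'
#' Identical machinery to [motion_regress()] with a user-supplied covariate
#' (e.g. intracranial volume, or global FC for sensitivity analyses).
#'
#' @param stack an [fc_stack()].
#' @param covariate per-scan covariate values.
#' @param name covariate label recorded in the provenance flags.
#' @return A covariate-corrected `fc_stack`.
#' @export
covariate_regress <- function(stack, covariate, name = "covariate") {
  if (nrow(stack$values) < 3) stop_maturind("need at least 3 scans")
  out <- stack
  out$values <- regress_stack(stack$values, covariate)
  out$provenance$covariates <- c(stack$provenance$covariates, name)
  out
}

#' Global signal regression
#'
#' Replaces each regional time series by the residuals of its regression on
#' the cross-region mean series.
#'
#' @param ts regions x timepoints matrix.
#' @return Matrix of residual series, same shape.
#' @export
gsr <- function(ts) {
  if (nrow(ts) < 2) stop_maturind("need at least 2 regions")
  g <- colMeans(ts)
  if (sd(g) == 0) stop_maturind("global signal has zero variance")
  gc <- g - mean(g)
  # residuals of y ~ 1 + g per region: y - a - b g with a = ybar - b gbar
  b <- drop(ts %*% gc) / sum(gc^2)
  a <- rowMeans(ts) - b * mean(g)
  out <- ts - outer(b, g) - matrix(a, nrow(ts), ncol(ts))
  dimnames(out) <- dimnames(ts)
  out
}

#' Nodal weighted degree of a connectivity matrix
#'
#' The mean edge weight of each node over its connections:
#' `k_i = (1/(N-1)) * sum_{j != i} w_ij`.
#'
#' @param fc symmetric Fisher-z matrix (diagonal ignored).
#' @return A tibble with columns `region`, `degree`.
#' @export
weighted_degree <- function(fc) {
  if (nrow(fc) < 2) stop_maturind("need at least 2 regions")
  d <- fc
  diag(d) <- 0
  tibble::tibble(
    region = rownames(fc) %||% as.character(seq_len(nrow(fc))),
    degree = unname(rowSums(d)) / (nrow(fc) - 1)
  )
}

#' Per-scan nodal weighted degree from an `fc_stack`
#'
#' @param stack an [fc_stack()].
#' @return scans x regions matrix of weighted degrees.
#' @export
stack_degrees <- function(stack) {
  n <- length(stack$regions)
  inc <- matrix(0, ncol(stack$values), n,
                dimnames = list(NULL, stack$regions))
  ia <- match(stack$edges$region_a, stack$regions)
  ib <- match(stack$edges$region_b, stack$regions)
  inc[cbind(seq_len(nrow(stack$edges)), ia)] <- 1
  inc[cbind(seq_len(nrow(stack$edges)), ib)] <- 1
  (stack$values %*% inc) / (n - 1)
}

#' Per-scan global FC (mean weighted degree over nodes)
#'
#' Equal to the mean of all off-diagonal Fisher-z entries of each scan.
#'
#' @param stack an [fc_stack()].
#' @return A tibble with columns `scan_id`, `global_fc`.
#' @export
global_fc <- function(stack) {
  tibble::tibble(scan_id = stack$scan_id,
                 global_fc = unname(rowMeans(stack$values)))
}

#' Block means of a connectivity matrix under a partition
#'
#' For each node and each class of the partition, the mean edge weight from
#' that node to members of the class (self excluded). With a single class this
#' reduces to the weighted degree.
#'
#' @param fc symmetric Fisher-z matrix with region dimnames.
#' @param partition named character vector or tibble (`region`, `class`)
#'   labelling every region.
#' @return A tibble `region`, `class`, `mean_fc`.
#' @export
block_means <- function(fc, partition) {
  if (is.data.frame(partition)) {
    partition <- setNames(as.character(partition$class), partition$region)
  }
  regions <- rownames(fc)
  if (!all(regions %in% names(partition))) {
    stop_maturind("every region must be labelled by the partition")
  }
  cls <- partition[regions]
  classes <- unique(cls)
  purrr::map_dfr(classes, function(cl) {
    members <- regions[cls == cl]
    means <- vapply(regions, function(r) {
      partners <- setdiff(members, r)
      if (length(partners) == 0) {
        stop_maturind("class '%s' has no partners for region %s", cl, r)
      }
      mean(fc[r, partners])
    }, numeric(1))
    tibble::tibble(region = regions, class = cl, mean_fc = unname(means))
  })
}
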