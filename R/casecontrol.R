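#' Case-control t map of nodal weighted degree
#'
#' Per region, the two-sample t statistic for case minus control nodal
#' weighted degree (negative t = reduced degree in cases). Welch's
#' unequal-variance t is the default.
#'
#' @param degrees subjects x regions matrix of weighted degrees.
#' @param labels tibble `subject`, `group` with group in `{"case",
#'   "control"}` (at least 2 subjects per group).
#' @param variant `"welch"` (default) or `"student"`.
#' @return A regional-map tibble `region`, `value` (t statistic), plus `df`
#'   and `p` columns.
#' @export
degree_tmap <- function(degrees, labels, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (!all(labels$subject %in% rownames(degrees))) {
    stop_maturind("labels reference subjects missing from the degree matrix")
  }
  grp <- setNames(labels$group, labels$subject)[rownames(degrees)]
  if (!all(grp %in% c("case", "control"))) {
    stop_maturind("group labels must be 'case' or 'control'")
  }
  n1 <- sum(grp == "case"); n0 <- sum(grp == "control")
  if (n1 < 2 || n0 < 2) stop_maturind("need at least 2 subjects per group")
  x1 <- degrees[grp == "case", , drop = FALSE]
  x0 <- degrees[grp == "control", , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  both_zero <- v1 == 0 & v0 == 0
  if (any(both_zero)) {
    stop_maturind("zero variance in both groups at region(s): %s",
                  paste(head(colnames(degrees)[both_zero], 5), collapse = ", "))
  }
  if (variant == "welch") {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  }
  t_stat <- (m1 - m0) / se
  tibble::tibble(
    region = colnames(degrees),
    value = unname(t_stat),
    df = unname(df),
    p = unname(2 * pt(-abs(t_stat), df))
  )
}

#' Colocation of a case-control t map with a sex-difference map
#'
#' Spatial Pearson correlation of the unthresholded t map with a map of sex
#' differences in the maturational index, with parametric and spin-test p
#' values (delegates to [map_correlation()]).
#'
#' @param tmap regional t map (e.g. from [degree_tmap()]).
#' @param dmi_map regional sex-difference map.
#' @param spins a [spin_rotations()] ensemble.
#' @return A one-row tibble `r`, `p_param`, `p_spin`, `n_regions`, `n_perm`.
#' @export
colocate_with_dmi <- function(tmap, dmi_map, spins) {
  map_correlation(tmap, dmi_map, spins)
}
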