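#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_abline labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot per-node maturational indices
#'
#' Nodes ordered by MI with classical standard-error bars; positive values
#' indicate conservative, negative values disruptive development.
#'
#' @param object an `mi_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mi_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$mi) |>
    dplyr::mutate(region = factor(.data$region, levels = .data$region))
  ggplot(df, aes(x = .data$region, y = .data$mi)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(aes(ymin = .data$mi - .data$se_mi,
                               ymax = .data$mi + .data$se_mi), width = 0) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = NULL, y = "maturational index",
         title = sprintf("Maturational index (%s)", attr(object, "sex"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot sex differences in a developmental parameter
#'
#' Per-node female-minus-male differences against the Z statistic, with
#' FDR-significant nodes highlighted.
#'
#' @param object a `delta_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.delta_result <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$delta, y = .data$z, colour = .data$significant)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = 0, linetype = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "female - male", y = "Z",
         colour = "FDR-significant") +
    theme_minimal()
}

#' Plot PLS1 regional scores against the target map
#'
#' @param object a `pls1_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pls1_fit <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$score, y = .data$target)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    labs(x = "PLS1 regional score", y = "target map",
         title = sprintf("PLS1 explains %.1f%% of target variance",
                         100 * object$varexp)) +
    theme_minimal()
}

#' Plot a case-control colocation scatter
#'
#' @param tmap regional t map (see [degree_tmap()]).
#' @param dmi_map regional sex-difference map.
#' @return A ggplot of t statistics against the sex-difference map.
#' @export
plot_colocation <- function(tmap, dmi_map) {
  a <- as_regional_map(tmap)
  b <- as_regional_map(dmi_map)
  df <- dplyr::inner_join(a, b, by = "region", suffix = c("_t", "_dmi"))
  ggplot(df, aes(x = .data$value_dmi, y = .data$value_t)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    labs(x = "sex difference in maturational index",
         y = "case-control t (weighted degree)") +
    theme_minimal()
}
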