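#' Functional-connectivity stacks
#'
#' An `fc_stack` holds the edgewise Fisher-z connectivity of a whole cohort:
#' one row per scan, one column per unique region pair (edge). It is the
#' working container passed between the connectome and developmental-modelling
#' stages. Provenance flags record which corrections have been applied so that
#' downstream consumers (and the analysis report) can state exactly what the
#' numbers are.
#'
#' @param values numeric matrix, scans x edges, Fisher-z units.
#' @param regions character vector of region labels; edges are all unordered
#'   pairs in this order.
#' @param scan_id character vector of scan identifiers (row names).
#' @param provenance named list of flags (`fisher_z`, `fd_regressed`,
#'   `fd_mode`, `gsr`, `covariates`).
#'
#' @return An object of class `fc_stack`.
#' @export
fc_stack <- function(values, regions, scan_id,
                     provenance = list()) {
  et <- edge_table(regions)
  if (ncol(values) != nrow(et)) {
    stop_maturind("values has %d columns but %d regions imply %d edges",
                  ncol(values), length(regions), nrow(et))
  }
  if (nrow(values) != length(scan_id)) {
    stop_maturind("values has %d rows but %d scan ids supplied", nrow(values), length(scan_id))
  }
  dimnames(values) <- list(scan_id, et$edge)
  structure(
    list(
      values = values,
      regions = regions,
      edges = et,
      scan_id = scan_id,
      provenance = utils::modifyList(
        list(fisher_z = TRUE, fd_regressed = FALSE, fd_mode = NA_character_,
             gsr = FALSE, covariates = character(0)),
        provenance)
    ),
    class = "fc_stack"
  )
}

#' @export
print.fc_stack <- function(x, ...) {
  cat(sprintf("<fc_stack> %d scans x %d edges (%d regions)\n",
              nrow(x$values), ncol(x$values), length(x$regions)))
  flags <- x$provenance
  cat(sprintf("  fisher_z=%s fd_regressed=%s fd_mode=%s gsr=%s covariates=%s\n",
              flags$fisher_z, flags$fd_regressed, flags$fd_mode, flags$gsr,
              if (length(flags$covariates)) paste(flags$covariates, collapse = ",") else "none"))
  invisible(x)
}

#' Stack per-scan FC matrices into an `fc_stack`
#'
#' @param mats named list of symmetric Fisher-z matrices with identical region
#'   dimnames (one per scan; names are scan ids).
#' @param provenance see [fc_stack()].
#' @return An `fc_stack`.
#' @export
fc_stack_from_matrices <- function(mats, provenance = list()) {
  regions <- rownames(mats[[1]])
  vals <- do.call(rbind, lapply(mats, mat_to_edges, regions = regions))
  fc_stack(vals, regions, names(mats), provenance)
}

#' Extract one scan of an `fc_stack` as a symmetric matrix
#'
#' @param stack an `fc_stack`.
#' @param scan scan id or row index.
#' @return Symmetric Fisher-z matrix with `NA` diagonal.
#' @export
fc_matrix_of <- function(stack, scan) {
  edges_to_mat(stack$values[scan, ], stack$regions)
}

#' Tidy an `fc_stack` into a long tibble
#'
#' One row per scan x edge. Intended for small stacks (plots, examples);
#' modelling functions operate on the matrix form directly.
#'
#' @param x an `fc_stack`.
#' @param ... unused.
#' @return A tibble with columns `scan_id`, `edge`, `region_a`, `region_b`, `fc`.
#' @export
tidy.fc_stack <- function(x, ...) {
  tibble::tibble(
    scan_id = rep(x$scan_id, times = ncol(x$values)),
    edge = rep(x$edges$edge, each = nrow(x$values)),
    region_a = rep(x$edges$region_a, each = nrow(x$values)),
    region_b = rep(x$edges$region_b, each = nrow(x$values)),
    fc = as.vector(x$values)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.fc_stack <- function(x, ...) {
  tibble::tibble(
    n_scans = nrow(x$values),
    n_regions = length(x$regions),
    n_edges = ncol(x$values),
    mean_fc = mean(x$values),
    fd_regressed = x$provenance$fd_regressed,
    gsr = x$provenance$gsr
  )
}
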