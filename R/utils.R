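#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom stats cor cor.test lm median p.adjust pnorm pt qnorm quantile
#'   rnorm runif sd setNames var rexp
#' @importFrom utils head
NULL

# Abort with a consistent class so tests can target maturind errors.
stop_maturind <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "maturind_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Edge bookkeeping: regions are identified by ordered string labels; edges by
# "a|b" with a < b lexicographically in the region ordering supplied.
edge_table <- function(regions) {
  n <- length(regions)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)  # column-major: matches m[upper.tri(m)]
  tibble::tibble(
    edge = paste(regions[idx[, 1]], regions[idx[, 2]], sep = "|"),
    region_a = regions[idx[, 1]],
    region_b = regions[idx[, 2]]
  )
}

# Map a symmetric matrix (labels in dimnames) to the edge vector ordered as
# edge_table(regions), and back.
mat_to_edges <- function(m, regions = rownames(m)) {
  m <- m[regions, regions, drop = FALSE]
  m[upper.tri(m)]
}

edges_to_mat <- function(values, regions) {
  n <- length(regions)
  m <- matrix(0, n, n, dimnames = list(regions, regions))
  m[upper.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

check_probability <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_maturind("%s values must lie in [0, 1]", what)
  }
  invisible(p)
}

# Add-one empirical p-value: never exactly 0.
p_empirical <- function(null_stats, observed, two_sided = TRUE) {
  if (two_sided) {
    (1 + sum(abs(null_stats) >= abs(observed))) / (length(null_stats) + 1)
  } else {
    (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
  }
}

# Derive a child seed from a master seed; keeps results below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

as_regional_map <- function(map, value_col = "value") {
  if (is.numeric(map) && !is.null(names(map))) {
    return(tibble::tibble(region = names(map), value = unname(map)))
  }
  if (!is.data.frame(map) || !all(c("region", value_col) %in% names(map))) {
    stop_maturind("a regional map must be a named numeric vector or a data frame with columns 'region' and '%s'", value_col)
  }
  out <- tibble::tibble(region = as.character(map$region), value = map[[value_col]])
  if (anyDuplicated(out$region)) stop_maturind("regional map labels must be unique")
  if (any(!is.finite(out$value))) stop_maturind("regional map values must be finite")
  out
}

map_values <- function(map, regions) {
  m <- as_regional_map(map)
  missing <- setdiff(regions, m$region)
  if (length(missing) > 0) {
    stop_maturind("regional map is missing regions: %s", paste(head(missing, 5), collapse = ", "))
  }
  m$value[match(regions, m$region)]
}
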