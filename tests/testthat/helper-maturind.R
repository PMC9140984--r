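# Shared fixture builders. Everything is generated in code at test time.

# A small noise-free cohort: FC follows the planted trajectories exactly.
noise_free_config <- function(n_subjects = 40, n_cortical = 10, seed = 2,
                              ...) {
  cohort_config(
    n_subjects = n_subjects, n_regions_cortical = n_cortical,
    n_regions_subcortical = 0, sites = 1, site_sd = 0,
    subject_sd = 0, subject_global_sd = 0, noise_sd = 0, beta_fd = 0,
    fd_outlier_p = 0, seed = seed, ...
  )
}

# Symmetric random Fisher-z matrix with labelled regions.
random_fc_matrix <- function(n, seed = 1) {
  set.seed(seed)
  regions <- sprintf("r%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(regions, regions))
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2, 0.3, 0.2)
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

# Upper-triangle edge vector of a symmetric matrix (column-major, the
# package's edge ordering).
mat_to_edges_test <- function(m) m[upper.tri(m)]

# Independent rank-then-Pearson Spearman oracle.
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# Stack whose edge values are an arbitrary scans x edges matrix.
stack_from_values <- function(values, n_regions) {
  regions <- sprintf("r%02d", seq_len(n_regions))
  fc_stack(values, regions, sprintf("s%03d", seq_len(nrow(values))))
}

# Smooth correlated maps on a sphere: kernel-smoothed iid noise, shared
# smoothing length-scale, independent draws.
smooth_map <- function(coords, ell = 0.6) {
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  k <- exp(-pmax(d2, 0) / (2 * ell^2))
  setNames(drop(k %*% rnorm(nrow(xyz))), coords$region)
}
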