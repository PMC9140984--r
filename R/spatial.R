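# Spatially constrained permutation inference. Cortical maps are permuted by
# random spherical rotations of the region centroids (the "spin" test), which
# preserves their spatial autocorrelation; subcortical regions, which have no
# surface coordinates, are permuted uniformly at random and independently.

# Haar-uniform random rotation via QR of a Gaussian matrix, det +1.
random_rotation <- function() {
  qr_m <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_m)
  q <- q %*% diag(sign(diag(qr.R(qr_m))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Greedy bijective assignment: each original region is mapped to the nearest
# unassigned rotated region, resolving globally smallest distances first, so
# the result is always a valid permutation.
greedy_assign <- function(original, rotated) {
  d <- outer(rowSums(original^2), rowSums(rotated^2), `+`) -
    2 * tcrossprod(original, rotated)
  n <- nrow(d)
  perm <- integer(n)
  for (i in seq_len(n)) {
    idx <- arrayInd(which.min(d), dim(d))
    perm[idx[1]] <- idx[2]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  perm
}

# Permutation induced by one rotation: left hemisphere rotated by rot, right
# by its x-mirror, preserving left/right correspondence.
spin_permutation <- function(xyz, hemi, rot) {
  mirror <- diag(c(-1, 1, 1))
  perm <- integer(nrow(xyz))
  for (h in unique(hemi)) {
    sel <- which(hemi == h)
    r_h <- if (h == unique(hemi)[1]) rot else mirror %*% rot %*% mirror
    rotated <- xyz[sel, , drop = FALSE] %*% t(r_h)
    perm[sel] <- sel[greedy_assign(xyz[sel, , drop = FALSE], rotated)]
  }
  perm
}

#' Generate a spin-permutation ensemble
#'
#' Draws `n_perm` uniform random rotations of the sphere; each rotation is
#' applied to one hemisphere and its mirror image to the other, and every
#' region is reassigned to its nearest rotated neighbour under a greedy
#' bijective matching, so each draw is a valid permutation of the cortical
#' labels. Subcortical labels, if supplied, receive independent uniform
#' permutations.
#'
#' @param coords tibble `region`, `hemisphere`, `x`, `y`, `z` with unit-norm
#'   coordinates (see [simulate_sphere_coords()]).
#' @param n_perm number of permutations (10,000 for production inference;
#'   smaller ensembles are appropriate for calibration experiments).
#' @param seed integer seed.
#' @param subcortical optional character vector of subcortical labels.
#' @return A `spin_ensemble`: cortical labels and an `n_perm` x n integer
#'   permutation matrix (plus the subcortical analogue when requested).
#' @export
spin_rotations <- function(coords, n_perm, seed = 1L, subcortical = character(0)) {
  if (nrow(coords) < 3) stop_maturind("need at least 3 cortical regions")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  norms <- sqrt(rowSums(xyz^2))
  if (any(abs(norms - 1) > 1e-6)) stop_maturind("coordinates must lie on the unit sphere")
  set.seed(as.integer(seed))
  perms <- matrix(0L, n_perm, nrow(coords))
  for (k in seq_len(n_perm)) {
    perms[k, ] <- spin_permutation(xyz, coords$hemisphere, random_rotation())
  }
  sub_perms <- NULL
  if (length(subcortical) > 0) {
    sub_perms <- t(vapply(seq_len(n_perm),
                          function(k) sample.int(length(subcortical)),
                          integer(length(subcortical))))
  }
  structure(list(
    labels_cortical = coords$region,
    labels_subcortical = subcortical,
    perms_cortical = perms,
    perms_subcortical = sub_perms,
    n_perm = n_perm, seed = as.integer(seed)
  ), class = "spin_ensemble")
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d permutations of %d cortical regions (%d subcortical), seed %d\n",
              x$n_perm, length(x$labels_cortical), length(x$labels_subcortical), x$seed))
  invisible(x)
}

# Values of `map` aligned to the ensemble's label order, and the matrix of
# permuted versions (regions x n_perm). A cortical-only map against an
# ensemble that also carries subcortical labels uses the cortical spins alone.
spin_align <- function(map, spins) {
  m <- as_regional_map(map)
  if (length(spins$labels_subcortical) > 0 &&
      !any(spins$labels_subcortical %in% m$region)) {
    spins$labels_subcortical <- character(0)
    spins$perms_subcortical <- NULL
  }
  labels <- c(spins$labels_cortical, spins$labels_subcortical)
  v <- map_values(map, labels)
  n_ctx <- length(spins$labels_cortical)
  permuted <- matrix(0, length(labels), spins$n_perm)
  vc <- v[seq_len(n_ctx)]
  permuted[seq_len(n_ctx), ] <- vc[t(spins$perms_cortical)]
  if (length(spins$labels_subcortical) > 0) {
    vs <- v[-seq_len(n_ctx)]
    permuted[-seq_len(n_ctx), ] <- vs[t(spins$perms_subcortical)]
  }
  list(values = v, permuted = permuted, labels = labels)
}

#' Spatial correlation of two regional maps with a spin-test p value
#'
#' Pearson correlation across regions, with a parametric p value from the t
#' distribution and a spin-permutation p value that preserves spatial
#' autocorrelation. The permutation is applied in both directions (each map
#' spun against the other's empirical version) and the two add-one empirical
#' p values, `(1 + #{|r_null| >= |r|})/(n_perm + 1)`, are averaged.
#'
#' @param map_a,map_b regional maps (named vectors or tibbles `region`,
#'   `value`) over the ensemble's labels.
#' @param spins a [spin_rotations()] ensemble.
#' @return A one-row tibble `r`, `p_param`, `p_spin`, `n_regions`, `n_perm`.
#' @export
map_correlation <- function(map_a, map_b, spins) {
  a <- spin_align(map_a, spins)
  b <- spin_align(map_b, spins)
  if (sd(a$values) == 0 || sd(b$values) == 0) {
    stop_maturind("zero-variance map")
  }
  r <- cor(a$values, b$values)
  p_param <- cor.test(a$values, b$values)$p.value
  null_a <- as.vector(cor(a$permuted, b$values))
  null_b <- as.vector(cor(b$permuted, a$values))
  p_spin <- mean(c(p_empirical(null_a, r), p_empirical(null_b, r)))
  tibble::tibble(r = r, p_param = p_param, p_spin = p_spin,
                 n_regions = length(a$values), n_perm = spins$n_perm)
}

#' Class means of a regional map under a partition
#'
#' @param map regional map (named vector or tibble `region`, `value`).
#' @param partition named character vector or tibble (`region`, `class`)
#'   labelling every region of the map.
#' @return A tibble `class`, `mean_value`, `n_regions`.
#' @export
partition_summary <- function(map, partition) {
  m <- as_regional_map(map)
  if (is.data.frame(partition)) {
    partition <- setNames(as.character(partition$class), partition$region)
  }
  if (!all(m$region %in% names(partition))) {
    stop_maturind("every region must be labelled by the partition")
  }
  cls <- partition[m$region]
  empty <- setdiff(unique(unname(partition)), unique(cls))
  if (length(empty) > 0) {
    stop_maturind("empty class(es): %s", paste(empty, collapse = ", "))
  }
  m |>
    dplyr::mutate(class = unname(cls)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_value = mean(.data$value), n_regions = dplyr::n(),
                     .groups = "drop")
}
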