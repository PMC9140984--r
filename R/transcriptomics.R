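# PLS mapping of a regional map onto regional gene expression, gene ranking,
# and median-rank gene-set enrichment against size- and length-matched nulls.
#
# With a univariate response the first PLS component has a closed form: the
# gene-weight vector is proportional to the covariance between each
# (standardised) gene's regional expression and the target map. Scores are
# the expression projected onto those weights.

# Column-wise Pearson correlation between matching columns of two matrices.
col_cor <- function(a, b) {
  a <- scale(a); b <- scale(b)
  colSums(a * b) / (nrow(a) - 1)
}

prepare_pls_inputs <- function(expression, target, scale_genes) {
  tm <- as_regional_map(target)
  common <- intersect(rownames(expression), tm$region)
  if (length(common) < 3) stop_maturind("fewer than 3 regions shared by expression and target")
  x <- expression[common, , drop = FALSE]
  y <- map_values(tm, common)
  if (sd(y) == 0) stop_maturind("target map has zero variance over shared regions")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop_maturind("zero-variance gene(s): %s",
                  paste(head(colnames(x)[sds == 0], 5), collapse = ", "))
  }
  x <- scale(x, center = TRUE, scale = scale_genes)
  list(x = x, y = y, regions = common)
}

pls1_core <- function(x, yc) {
  w <- crossprod(x, yc)
  w <- w / sqrt(sum(w^2))
  scores <- drop(x %*% w)
  r <- cor(scores, yc)
  if (r < 0) {  # orient the component so scores track the target positively
    w <- -w; scores <- -scores; r <- -r
  }
  list(weights = drop(w), scores = scores, varexp = r^2)
}

#' First partial least squares component of a map on gene expression
#'
#' Extracts the first component (PLS1) of a PLS regression of a regional
#' target map on a regions x genes expression panel. Genes are standardised
#' across regions by default. The component is sign-anchored so that regional
#' scores correlate positively with the target; variance explained is the
#' squared correlation between scores and target (i.e. variance in the
#' target, not in expression).
#'
#' @param expression regions x genes matrix with region rownames and gene
#'   colnames.
#' @param target regional map (named vector or tibble `region`, `value`).
#' @param scale_genes standardise each gene to unit SD (default TRUE).
#' @return A `pls1_fit`: list with `weights` (tibble `gene`, `weight`),
#'   `scores` (tibble `region`, `score`, `target`), `varexp`, `n_regions`,
#'   `n_genes`.
#' @export
pls1 <- function(expression, target, scale_genes = TRUE) {
  inp <- prepare_pls_inputs(expression, target, scale_genes)
  fit <- pls1_core(inp$x, inp$y - mean(inp$y))
  structure(list(
    weights = tibble::tibble(gene = colnames(inp$x), weight = unname(fit$weights)),
    scores = tibble::tibble(region = inp$regions, score = fit$scores,
                            target = inp$y),
    varexp = fit$varexp,
    n_regions = length(inp$regions),
    n_genes = ncol(inp$x)
  ), class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("<pls1_fit> %d regions x %d genes; variance explained in target: %.1f%%\n",
              x$n_regions, x$n_genes, 100 * x$varexp))
  invisible(x)
}

#' @export
tidy.pls1_fit <- function(x, ...) x$weights

#' @export
glance.pls1_fit <- function(x, ...) {
  tibble::tibble(varexp = x$varexp, n_regions = x$n_regions, n_genes = x$n_genes)
}

#' Permutation significance of the PLS1 variance explained
#'
#' Compares the observed variance explained against (a) unconstrained random
#' permutations of the target and (b) spatial-autocorrelation-preserving spin
#' permutations, both as add-one empirical p values.
#'
#' @param expression regions x genes matrix.
#' @param target regional map.
#' @param spins a [spin_rotations()] ensemble covering the target's labels.
#' @param n_perm number of unconstrained permutations (default 1000).
#' @param seed seed for the unconstrained permutations.
#' @param scale_genes standardise genes (as in [pls1()]).
#' @return A one-row tibble `varexp`, `p_perm`, `p_spin`.
#' @export
pls1_significance <- function(expression, target, spins, n_perm = 1000,
                              seed = 1L, scale_genes = TRUE) {
  inp <- prepare_pls_inputs(expression, target, scale_genes)
  yc <- inp$y - mean(inp$y)
  observed <- pls1_core(inp$x, yc)$varexp

  varexp_many <- function(y_mat) {
    y_mat <- scale(y_mat, center = TRUE, scale = FALSE)
    scores <- inp$x %*% crossprod(inp$x, y_mat)  # per-column PLS1 scores (unnormalised)
    col_cor(scores, y_mat)^2
  }
  set.seed(as.integer(seed))
  y_perm <- vapply(seq_len(n_perm), function(k) inp$y[sample.int(length(inp$y))],
                   numeric(length(inp$y)))
  null_perm <- varexp_many(y_perm)

  aligned <- spin_align(as_regional_map(target), spins)
  keep <- match(inp$regions, aligned$labels)
  null_spin <- varexp_many(aligned$permuted[keep, , drop = FALSE])

  tibble::tibble(
    varexp = observed,
    p_perm = p_empirical(null_perm, observed, two_sided = FALSE),
    p_spin = p_empirical(null_spin, observed, two_sided = FALSE)
  )
}

#' Rank genes by PLS1 weight
#'
#' Ascending by weight: rank 1 is the most negatively weighted gene (most
#' strongly expressed where the target map is most negative). Ties are broken
#' alphabetically by gene symbol, so the ranking is a deterministic function
#' of the weights.
#'
#' @param pls a `pls1_fit` (or a tibble with columns `gene`, `weight`).
#' @return A tibble `gene`, `weight`, `rank`.
#' @export
rank_genes <- function(pls) {
  w <- if (inherits(pls, "pls1_fit")) pls$weights else pls
  if (any(!is.finite(w$weight))) stop_maturind("weights must be finite")
  w |>
    dplyr::arrange(.data$weight, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
}

length_bins <- function(gene_table, n_bins = 10) {
  dplyr::mutate(gene_table,
                .bin = dplyr::ntile(log10(.data$length), n_bins))
}

#' Median-rank gene-set enrichment with matched nulls
#'
#' Tests whether a reference gene set sits unusually low (bottom: negative
#' weights) or high (top) in a ranked gene list. The observed median rank is
#' compared with `n_null` random sets matched to the reference set in size
#' and gene length: each null gene is drawn from the same decile bin of
#' log10(gene length) as the corresponding reference gene.
#'
#' @param ranking ranked list from [rank_genes()].
#' @param gene_set character vector of gene symbols (must all be in the
#'   ranking).
#' @param gene_table tibble `gene`, `length` (and optionally `chromosome`)
#'   covering the ranking.
#' @param n_null number of null sets (default 10,000).
#' @param seed integer seed (mandatory for reproducible nulls).
#' @return A one-row tibble: `n_genes`, `observed_median`, `null_median`,
#'   `p` (two-sided, add-one), `direction` (`"bottom"` or `"top"`).
#' @export
median_rank_enrichment <- function(ranking, gene_set, gene_table,
                                   n_null = 10000, seed = 1L) {
  if (length(gene_set) == 0) stop_maturind("gene_set is empty")
  unknown <- setdiff(gene_set, ranking$gene)
  if (length(unknown) > 0) {
    stop_maturind("gene_set members missing from ranking: %s",
                  paste(head(unknown, 5), collapse = ", "))
  }
  tbl <- dplyr::inner_join(ranking, gene_table, by = "gene")
  if (nrow(tbl) < nrow(ranking)) {
    missing <- setdiff(ranking$gene, gene_table$gene)
    stop_maturind("gene lengths missing for: %s", paste(head(missing, 5), collapse = ", "))
  }
  tbl <- length_bins(tbl)
  observed <- median(tbl$rank[tbl$gene %in% gene_set])
  set.seed(as.integer(seed))
  set_bins <- tbl$.bin[match(gene_set, tbl$gene)]
  null_ranks <- matrix(0, length(gene_set), n_null)
  row0 <- 0
  for (b in sort(unique(set_bins))) {
    k_b <- sum(set_bins == b)
    pool <- tbl$rank[tbl$.bin == b]
    null_ranks[row0 + seq_len(k_b), ] <- sample(pool, k_b * n_null, replace = TRUE)
    row0 <- row0 + k_b
  }
  null_medians <- apply(null_ranks, 2, median)
  p_lo <- (1 + sum(null_medians <= observed)) / (n_null + 1)
  p_hi <- (1 + sum(null_medians >= observed)) / (n_null + 1)
  tibble::tibble(
    n_genes = length(gene_set),
    observed_median = observed,
    null_median = median(null_medians),
    p = min(1, 2 * min(p_lo, p_hi)),
    direction = if (observed < median(null_medians)) "bottom" else "top"
  )
}

#' Per-chromosome median ranks with permutation p values
#'
#' For each chromosome, the median rank of its genes in the ranked list and a
#' two-sided add-one p value against `n_null` random gene sets of the same
#' size (length-matched sampling optional).
#'
#' @param ranking ranked list from [rank_genes()].
#' @param gene_table tibble `gene`, `chromosome`, `length`.
#' @param n_null number of null sets per chromosome (default 10,000).
#' @param seed integer seed.
#' @param length_match also match null genes on log-length decile.
#' @return A tibble `chromosome`, `n_genes`, `median_rank`, `p`, sorted by
#'   median rank.
#' @export
chromosome_profile <- function(ranking, gene_table, n_null = 10000, seed = 1L,
                               length_match = FALSE) {
  tbl <- dplyr::inner_join(ranking, gene_table, by = "gene")
  chroms <- unique(tbl$chromosome)
  absent <- setdiff(unique(gene_table$chromosome), chroms)
  if (length(absent) > 0) {
    warn(sprintf("chromosome(s) with no ranked genes skipped: %s",
                 paste(absent, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  purrr::map_dfr(chroms, function(ch) {
    genes_ch <- tbl$gene[tbl$chromosome == ch]
    if (length_match) {
      res <- median_rank_enrichment(ranking, genes_ch, gene_table,
                                    n_null = n_null,
                                    seed = sample.int(2^30, 1))
      tibble::tibble(chromosome = ch, n_genes = res$n_genes,
                     median_rank = res$observed_median, p = res$p)
    } else {
      k <- length(genes_ch)
      observed <- median(tbl$rank[tbl$chromosome == ch])
      null_ranks <- matrix(sample(tbl$rank, k * n_null, replace = TRUE), k, n_null)
      null_medians <- apply(null_ranks, 2, median)
      p_lo <- (1 + sum(null_medians <= observed)) / (n_null + 1)
      p_hi <- (1 + sum(null_medians >= observed)) / (n_null + 1)
      tibble::tibble(chromosome = ch, n_genes = k, median_rank = observed,
                     p = min(1, 2 * min(p_lo, p_hi)))
    }
  }) |>
    dplyr::arrange(.data$median_rank)
}
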