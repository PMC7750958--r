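#' Scaled PCA on ID allele frequencies
#'
#' Principal component analysis of the ID frequency columns of a frequency
#' matrix, each column centered and scaled to unit variance, so every ID
#' contributes identical variance before decomposition. The FL column is
#' excluded (it is the complement of the IDs and adds no information);
#' constant columns are dropped with a warning; `exclude` removes named
#' alleles (for example the KP element, `"ID_808_2560"`) before the
#' decomposition. Each loading vector is oriented so its largest-magnitude
#' entry is positive.
#'
#' @param matrix A frequency matrix (private IDs already dropped).
#' @param exclude Character vector of allele columns to leave out.
#' @return An `id_pca` object: list with `scores` (tibble `sample_id` +
#'   `PC1..`), `loadings` (tibble `allele` + `PC1..`), `variance_fraction`,
#'   and `contributions` (per-allele squared-loading share of each PC,
#'   summing to 1 per component).
#' @export
scaled_pca <- function(matrix, exclude = NULL) {
  ids <- setdiff(id_allele_cols(matrix), exclude)
  if (nrow(matrix) < 3) abort("need at least 3 samples")
  x <- as.matrix(matrix[, ids, drop = FALSE])
  rownames(x) <- matrix$sample_id
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) abort("all allele columns are constant")
  if (any(!keep)) {
    warn(sprintf("dropping %d constant allele column(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2) abort("need at least 2 non-constant allele columns")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # orient each component so its largest-magnitude loading is positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  fit$rotation <- sweep(fit$rotation, 2, flip, `*`)
  fit$x <- sweep(fit$x, 2, flip, `*`)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  contrib <- sweep(fit$rotation^2, 2, colSums(fit$rotation^2), `/`)
  structure(
    list(
      scores = bind_cols(tibble(sample_id = matrix$sample_id),
                         as_tibble(fit$x)),
      loadings = bind_cols(tibble(allele = colnames(x)),
                           as_tibble(fit$rotation)),
      variance_fraction = stats::setNames(var_frac, colnames(fit$x)),
      contributions = bind_cols(tibble(allele = colnames(x)),
                                as_tibble(contrib)),
      sdev = fit$sdev
    ),
    class = "id_pca"
  )
}

#' @export
print.id_pca <- function(x, ...) {
  cat(sprintf("<id_pca> %d samples x %d alleles; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$variance_fraction[1],
              100 * if (length(x$variance_fraction) > 1) x$variance_fraction[2] else NA))
  invisible(x)
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper off-diagonal triangles of two distance
#' matrices; the null distribution permutes the rows and columns of `d2`
#' simultaneously. The one-sided p-value (positive association) uses add-one
#' smoothing: `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @param d1,d2 Symmetric matrices over the same labels in the same order.
#' @param n_perm Number of permutations.
#' @return A `mantel_result`: list with `statistic` (r), `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999) {
  if (inherits(d1, "dist")) d1 <- as.matrix(d1)
  if (inherits(d2, "dist")) d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) abort("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    abort("distance matrices must share labels in the same order")
  }
  if (n_perm < 1) abort("need at least one permutation")
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r_obs <- stats::cor(v1, d2[ut])
  n <- nrow(d1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(v1, d2[p, p][ut]) >= r_obs) hits <- hits + 1L
  }
  structure(list(statistic = r_obs, p_value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, one-sided)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Permutation test for group-specific clades
#'
#' Tests how surprising it is that an observed tree assigns samples to
#' group-specific clades: the statistic is whether a random equal-size
#' partition of the samples reproduces the observed partition up to
#' relabeling of the groups. With `exact = TRUE` the probability is the
#' closed-form count `g! * prod(s_i!) / n!` of permutations matching the
#' partition; otherwise random partitions are drawn and the add-one smoothed
#' permutation p-value is returned.
#'
#' @param partition List of character vectors (the observed grouping), or a
#'   named vector mapping sample to group.
#' @param n_perm Number of random partitions when `exact = FALSE`.
#' @param exact Use the combinatorial closed form.
#' @return p-value.
#' @examples
#' groups <- split(paste0("s", 1:15), rep(1:3, each = 5))
#' clade_permutation_test(groups, exact = TRUE)  # 6/756756
#' @export
clade_permutation_test <- function(partition, n_perm = 100000, exact = FALSE) {
  if (!is.list(partition)) partition <- split(names(partition), partition)
  sizes <- vapply(partition, length, integer(1))
  n <- sum(sizes)
  g <- length(partition)
  if (length(unique(sizes)) != 1) {
    abort("groups must have equal sizes")
  }
  if (exact) {
    # P(uniform equal-size partition == observed up to group relabeling)
    log_p <- lgamma(g + 1) + sum(lgamma(sizes + 1)) - lgamma(n + 1)
    return(exp(log_p))
  }
  samples <- unlist(partition, use.names = FALSE)
  canon <- function(groups) {
    paste(sort(vapply(groups, function(gr) paste(sort(gr), collapse = ","),
                      character(1))), collapse = ";")
  }
  obs <- canon(partition)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    shuffled <- split(sample(samples), rep(seq_len(g), times = sizes))
    if (canon(shuffled) == obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Conjugate posterior for per-split recovery probability
#'
#' Shared-split counts are modeled as binomial draws with `n_max` trials (the
#' maximum attainable shared splits, `n - 3` for `n` tips) and a flat
#' Beta(1, 1) prior on the recovery probability `p`. The posterior is the
#' conjugate `Beta(1 + sum(k), 1 + T * n_max - sum(k))` for `T` observed
#' trees, reported with its mean and central 95% credible interval.
#'
#' @param shared_counts Integer vector of shared-split counts, one per tree.
#' @param n_max Maximum possible shared splits per tree.
#' @return A `split_posterior`: list with `alpha`, `beta`, `mean`, `ci95`,
#'   `n_trees`, `n_max`.
#' @examples
#' split_share_posterior(c(8), n_max = 8)  # Beta(9, 1), mean 0.9
#' @export
split_share_posterior <- function(shared_counts, n_max = 8) {
  if (any(shared_counts < 0 | shared_counts > n_max)) {
    abort("shared counts must lie in [0, n_max]")
  }
  k <- sum(shared_counts)
  t_trees <- length(shared_counts)
  alpha <- 1 + k
  beta <- 1 + t_trees * n_max - k
  structure(
    list(alpha = alpha, beta = beta,
         mean = alpha / (alpha + beta),
         ci95 = stats::qbeta(c(0.025, 0.975), alpha, beta),
         n_trees = t_trees, n_max = n_max),
    class = "split_posterior"
  )
}

#' @export
print.split_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior: mean %.4f, 95%% CI [%.4f, %.4f] (%d trees, n_max %d)\n",
              x$alpha, x$beta, x$mean, x$ci95[1], x$ci95[2], x$n_trees, x$n_max))
  invisible(x)
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances (in km) between sampling locations, for use as the
#' geographic side of a Mantel test.
#'
#' @param coords Tibble with columns `sample_id`, `lat`, `lon` (degrees).
#' @return Symmetric matrix of distances in km, labelled by `sample_id`.
#' @export
geo_distance_matrix <- function(coords) {
  stopifnot(all(c("sample_id", "lat", "lon") %in% names(coords)))
  m <- geosphere::distm(as.matrix(coords[, c("lon", "lat")]),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(coords$sample_id, coords$sample_id)
  m
}

#' Correlation of a principal component with a spatial coordinate
#'
#' Spearman's rank correlation (tie-corrected, t-approximation p-value)
#' between per-sample PC scores and latitude or longitude.
#'
#' @param pca An `id_pca` object.
#' @param coords Tibble with `sample_id` and the coordinate column.
#' @param component PC name, e.g. `"PC1"`.
#' @param coordinate Column in `coords`, e.g. `"lat"`.
#' @return Tibble with `rho` and `p_value`.
#' @export
pc_coordinate_correlation <- function(pca, coords, component = "PC1",
                                      coordinate = "lat") {
  merged <- dplyr::inner_join(pca$scores[, c("sample_id", component)],
                              coords[, c("sample_id", coordinate)],
                              by = "sample_id")
  ct <- stats::cor.test(merged[[component]], merged[[coordinate]],
                        method = "spearman", exact = FALSE)
  tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}
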