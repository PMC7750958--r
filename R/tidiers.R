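#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a split-recovery posterior
#'
#' @param x A `split_posterior`.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (posterior mean), `conf.low`,
#'   `conf.high` (central 95% credible interval).
#' @export
tidy.split_posterior <- function(x, ...) {
  tibble(term = "recovery_probability", estimate = x$mean,
         conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname tidy.split_posterior
#' @export
glance.split_posterior <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, n_trees = x$n_trees, n_max = x$n_max)
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(term = "mantel_r", estimate = x$statistic, p.value = x$p_value)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n_perm = x$n_perm)
}

#' Tidy a scaled PCA of ID frequencies
#'
#' @param x An `id_pca`.
#' @param matrix One of `"scores"`, `"loadings"`, `"contributions"`,
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.id_pca <- function(x, matrix = c("scores", "loadings", "contributions",
                                      "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"sample_id", names_to = "component",
                                 values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"allele",
                                   names_to = "component",
                                   values_to = "loading"),
    contributions = tidyr::pivot_longer(x$contributions, -"allele",
                                        names_to = "component",
                                        values_to = "contribution"),
    eigenvalues = tibble(component = names(x$variance_fraction),
                         variance_fraction = unname(x$variance_fraction))
  )
}

#' @rdname tidy.id_pca
#' @export
glance.id_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_alleles = nrow(x$loadings),
         pc1_variance = unname(x$variance_fraction[1]),
         pc2_variance = if (length(x$variance_fraction) > 1) {
           unname(x$variance_fraction[2])
         } else NA_real_)
}
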