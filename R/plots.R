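#' Plot invasion dynamics
#'
#' Time series of the mean diploid copy number and the fraction of copies
#' carrying an internal deletion, per population.
#'
#' @param object An `invasion` from [run_invasion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.invasion <- function(object, ...) {
  long <- object$records |>
    select("generation", "population", "copy_number", "fraction_id") |>
    tidyr::pivot_longer(c("copy_number", "fraction_id"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     colour = factor(.data$population))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1,
                        labeller = ggplot2::labeller(metric = c(
                          copy_number = "mean diploid copy number",
                          fraction_id = "fraction of ID copies"))) +
    ggplot2::labs(colour = "population", x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.invasion
#' @export
plot_invasion <- function(object, ...) autoplot.invasion(object, ...)

#' Plot PCA scores of ID frequencies
#'
#' @param object An `id_pca` from [scaled_pca()].
#' @param ... Unused.
#' @export
autoplot.id_pca <- function(object, ...) {
  vf <- object$variance_fraction
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}

#' MDS plot of a reconstruction
#'
#' @param object An `id_reconstruction` from [pipeline_reconstruct()], or the
#'   coordinate tibble of [classical_mds()].
#' @param ... Unused.
#' @export
autoplot.id_reconstruction <- function(object, ...) plot_mds(object$mds)

#' @rdname autoplot.id_reconstruction
#' @param coords MDS coordinate tibble.
#' @export
plot_mds <- function(coords, ...) {
  if (inherits(coords, "id_reconstruction")) coords <- coords$mds
  ggplot2::ggplot(coords, ggplot2::aes(.data$MDS1, .data$MDS2,
                                       label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2") +
    ggplot2::theme_minimal()
}

#' Fingerprint arc diagram
#'
#' Draws each ID of one sample as an arc spanning its deletion on the TE
#' consensus, line width scaled by frequency — the standard way to visualize
#' an ID fingerprint.
#'
#' @param fingerprint Tibble with `start`, `end`, `frequency` (one sample).
#' @param consensus_len Consensus length for the x axis.
#' @export
plot_fingerprint <- function(fingerprint, consensus_len = 2907) {
  fp <- as_tibble(fingerprint) |>
    mutate(mid = (.data$start + .data$end) / 2,
           half = (.data$end - .data$start) / 2,
           id = row_number())
  arcs <- fp |>
    dplyr::reframe(theta = seq(0, pi, length.out = 60),
                   x = .data$mid + .data$half * cos(.data$theta),
                   y = .data$half * sin(.data$theta) / consensus_len,
                   frequency = .data$frequency, .by = "id")
  ggplot2::ggplot(arcs, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                     linewidth = .data$frequency)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(x = "position on TE consensus (bp)", y = NULL,
                  linewidth = "frequency") +
    ggplot2::coord_cartesian(xlim = c(1, consensus_len)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
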