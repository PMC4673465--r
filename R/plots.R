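#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of PCA / PCoA coordinates
#'
#' First two components, points coloured by population.
#'
#' @param object a `pop_pca`.
#' @param components which two components to draw (default 1:2).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pop_pca <- function(object, components = c(1L, 2L), ...) {
  td <- tidy(object)
  axes <- colnames(object$coordinates)[components]
  ggplot2::ggplot(td, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                   colour = .data$population)) +
    ggplot2::geom_point(size = if (object$kind == "population") 3 else 1.5,
                        alpha = if (object$kind == "population") 1 else 0.7) +
    ggplot2::labs(title = paste0(object$kind, "-level principal coordinates"),
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise F_ST matrix
#'
#' @param object an `fst_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fst_matrix <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::bind_rows(td,
                         dplyr::rename(td, pop_i = "pop_j", pop_j = "pop_i"))
  ggplot2::ggplot(td, ggplot2::aes(.data$pop_i, .data$pop_j,
                                   fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[ST])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Major-haplotype frequency barchart
#'
#' Per-population frequencies of each major haplotype, the standard view
#' of how shared haplotypes differ in frequency across populations.
#'
#' @param object a `major_haplotypes` set.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.major_haplotypes <- function(object, ...) {
  freq <- object$catalog$freq[, object$haplotype, drop = FALSE]
  colnames(freq) <- object$label
  td <- tibble::tibble(
    population = rep(rownames(freq), times = ncol(freq)),
    haplotype = factor(rep(colnames(freq), each = nrow(freq)),
                       levels = object$label),
    freq = as.vector(freq)
  )
  ggplot2::ggplot(td, ggplot2::aes(.data$haplotype, .data$freq,
                                   fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "population frequency", x = NULL) +
    ggplot2::theme_minimal()
}

#' Discordance-rate dot plot for a panel comparison
#'
#' @param comparison tibble from [panel_comparison()].
#' @return A ggplot: discordance by reference panel, one facet per target
#'   population.
#' @export
plot_discordance <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(.data$panel, .data$discordance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target_pop)) +
    ggplot2::labs(x = "reference panel", y = expression(1 - r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
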