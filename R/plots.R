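#' Manhattan plot of an association scan
#'
#' One panel per trait, markers along the genome, `-log10(q)` on the
#' vertical axis with the FDR screen lines at 0.05 and 0.01.
#'
#' @param scan Output of [assoc_scan()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan) {
  df <- scan |>
    dplyr::filter(!is.na(.data$q)) |>
    dplyr::arrange(.data$chromosome, .data$position_bp) |>
    dplyr::mutate(idx = dplyr::row_number() /
                    dplyr::n_distinct(.data$trait))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_bp / 1e6,
                                   y = -log10(.data$q),
                                   colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(0.01), linetype = "dashed",
                        colour = "blue") +
    ggplot2::facet_grid(trait ~ chromosome, scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10(FDR)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Score plot of a PCA model
#'
#' @param object A [run_pca()] fit.
#' @param components Two component indices (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object: sample coordinates coloured by type, shaped
#'   by breed.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), ...) {
  df <- tidy(object, n_components = max(components))
  xs <- paste0("PC", components[1])
  ys <- paste0("PC", components[2])
  pct <- round(100 * object$var_explained[components], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                   colour = .data$type,
                                   shape = .data$breed)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = seq_len(
      dplyr::n_distinct(df$breed))) +
    ggplot2::labs(x = paste0(xs, " (", pct[1], "%)"),
                  y = paste0(ys, " (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Per-marker contribution plot for a scanned component
#'
#' pcaDObs along the genome with the selected markers highlighted.
#'
#' @param records Output of [pcadobs_significance()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$position_bp / 1e6,
                               y = .data$pcadobs,
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::facet_grid(~chromosome, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = "pcaDObs") +
    ggplot2::theme_minimal()
}
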