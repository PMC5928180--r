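#' Plot endmember spectra of a fitted model
#' @param object a `factor_model`. @param ... unused.
#' @return A ggplot: one line per endmember over the channel axis.
#' @method autoplot factor_model
#' @export
autoplot.factor_model <- function(object, ...) {
  df <- tidy(object, matrix = "endmembers")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "channel", y = "intensity",
                  title = sprintf("%s endmembers (k = %d)",
                                  toupper(object$method), ncol(object$U))) +
    ggplot2::theme_minimal()
}

#' Plot abundance maps of a fitted model
#' @param model a `factor_model` fitted to gridded pixels.
#' @return A ggplot raster facetted by endmember.
#' @export
plot_abundance_maps <- function(model) {
  df <- tidy(model, matrix = "abundances")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$abundance)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Abundance maps")
}

#' Plot rank-scan diagnostics
#' @param object a `rank_scan`. @param ... unused.
#' @return A ggplot with the three criteria facetted over k.
#' @method autoplot rank_scan
#' @export
autoplot.rank_scan <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"k", names_to = "criterion", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Rank-selection diagnostics")
}

#' Plot a residual map
#' @param res matrix from [residual_map()].
#' @return A ggplot raster.
#' @export
plot_residual_map <- function(res) {
  idx <- raster_index(dim(res))
  df <- tibble::tibble(y = idx[, "y"], x = idx[, "x"],
                       error = as.vector(t(res)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$error)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Per-pixel relative reconstruction error")
}
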