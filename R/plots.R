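#' Plot a land-use raster
#'
#' @param object An [lu_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lu_raster
#' @export
autoplot.lu_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$code))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_d(name = "class", na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a continuous surface (degradation or quality)
#'
#' @param object A [value_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot value_raster
#' @export
autoplot.value_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$what, na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a transfer matrix as a tile map of flows
#'
#' Off-diagonal tiles show area moving between classes; the diagonal is the
#' area that stayed.
#'
#' @param object A `transfer_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transfer_matrix
#' @export
autoplot.transfer_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from,
                                   fill = .data$area_km2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$area_km2, 3)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "km²", trans = "log1p") +
    ggplot2::labs(x = "to (second epoch)", y = "from (first epoch)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot detector results
#'
#' Bar chart of per-factor q (significant factors filled), with the pairwise
#' interaction q12 overlaid as points when present.
#'
#' @param object A `detector_report`.
#' @param alpha Significance threshold used for the fill.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detector_report
#' @export
autoplot.detector_report <- function(object, alpha = 0.05, ...) {
  fr <- object$factor
  fr$significant <- !is.na(fr$p_value) & fr$p_value < alpha
  ggplot2::ggplot(fr, ggplot2::aes(stats::reorder(.data$factor, -.data$q),
                                   .data$q, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = paste0("p < ", alpha)) +
    ggplot2::labs(x = NULL, y = "q (variance explained)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-grade area shares
#'
#' @param object A `graded_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot graded_raster
#' @export
autoplot.graded_raster <- function(object, ...) {
  df <- object$areas
  df$label <- factor(df$label, levels = object$levels)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$share_pct)) +
    ggplot2::geom_col(fill = "#41b6c4") +
    ggplot2::labs(x = paste(object$what, "grade"), y = "area share (%)") +
    ggplot2::theme_minimal()
}
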