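# ggplot2 views of the main result types.

grid_to_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Map a condition index grid
#'
#' @param object an `fc_condition_index`.
#' @param ... unused.
#' @return a ggplot raster map of the per-cell index.
#' @method autoplot fc_condition_index
#' @export
autoplot.fc_condition_index <- function(object, ...) {
  df <- grid_to_df(object$index, "index")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$index)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "condition\nindex") +
    ggplot2::theme_minimal()
}

#' Dot plot of per-type condition by accounting year
#'
#' Mirrors the account's headline figure: one row per forest type, the
#' index in each accounting year as points.
#'
#' @param account the account tibble from [build_account()].
#' @return a ggplot.
#' @export
plot_type_index <- function(account) {
  df <- dplyr::distinct(account, .data$type_id, .data$forest_class,
                        .data$region, .data$year, .data$index)
  df$label <- paste(df$region, df$forest_class)
  ggplot2::ggplot(df, ggplot2::aes(.data$index,
                                   stats::reorder(.data$label,
                                                  .data$index),
                                   colour = .data$year)) +
    ggplot2::geom_point() +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "forest condition index", y = NULL,
                  colour = "year") +
    ggplot2::theme_minimal()
}

#' Bar chart of the sensitivity analysis averaged over types
#'
#' @param object an `fc_oat` tibble from [run_oat()].
#' @param ... unused.
#' @return a ggplot of mean percentage deviation per parameter.
#' @method autoplot fc_oat
#' @export
autoplot.fc_oat <- function(object, ...) {
  df <- summarize_oat(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$indicator,
                                   .data$mean_pct_deviation,
                                   fill = .data$parameter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "index deviation (%)",
                  fill = "parameter") +
    ggplot2::theme_minimal()
}
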