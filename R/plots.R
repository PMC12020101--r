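#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of compound scores for one parameter
#'
#' The screen's standard per-parameter view: every compound's SD-distance
#' score against its library position, with the hit threshold drawn as a
#' horizontal line and called hits highlighted.
#'
#' @param object A `plate_scores` tibble from [score_plate()].
#' @param parameter Which of [ld_params()] to display.
#' @param hits Optional `hit_table` from [call_hits()]; called hits are
#'   coloured.
#' @param threshold Threshold line(s) to draw; defaults to the parameter's
#'   default calling threshold, signed by the default direction.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plate_scores
#' @export
autoplot.plate_scores <- function(object, parameter = "ld_total_area",
                                  hits = NULL, threshold = NULL, ...) {
  stopifnot(parameter %in% levels(object$parameter))
  df <- as_tibble(object) %>%
    filter(.data$parameter == !!parameter) %>%
    arrange(.data$compound_id) %>%
    mutate(index = dplyr::row_number(), hit = FALSE)
  if (!is.null(hits)) {
    df$hit <- df$compound_id %in% hits$compound_id[hits$hit]
  }
  if (is.null(threshold)) {
    thr <- default_thresholds()[[parameter]]
    threshold <- switch(default_directions()[[parameter]],
                        decrease = -thr, increase = thr, c(-thr, thr))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hit), size = 1.2,
                        show.legend = any(df$hit)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "goldenrod"),
                                 name = "hit") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "compound", y = "score (SD from sample median)",
                  title = parameter) +
    ggplot2::theme_minimal()
}

#' Plate-layout role map
#'
#' Tile view of a plate map: one tile per well coloured by role. Useful to
#' sanity-check layouts read from CSV.
#'
#' @param layout A layout tibble ([plate_layout()] / [read_plate_map()]).
#' @return A ggplot object.
#' @export
plot_plate_layout <- function(layout) {
  validate_layout(layout)
  ggplot2::ggplot(layout, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$role)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse(breaks = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a rendered field channel
#'
#' @param img An `image_set`.
#' @param channel Channel name to show.
#' @return A ggplot object (raster heat map).
#' @export
plot_field <- function(img, channel = "puncta") {
  stopifnot(inherits(img, "image_set"), channel %in% names(img$channels))
  m <- img$channels[[channel]]
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$intensity <- as.vector(t(m))[(df$y - 1) * ncol(m) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = channel, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
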