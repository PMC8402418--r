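#' Plot an AGGIR assessment as a day-by-variable grid
#'
#' Each tile shows the detected count for one (day, variable) cell, filled
#' by whether the day passed the variable's criterion — the graphical twin
#' of the weekly report.
#'
#' @param object An `aggir_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aggir_assessment
#' @export
autoplot.aggir_assessment <- function(object, ...) {
  d <- object$days
  d$label <- factor(day_label(d$day), levels = unique(day_label(sort(unique(d$day)))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$variable,
                                  fill = .data$pass)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_detected), size = 3.4) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#7fbf7b", `FALSE` = "#e08214"),
                               name = "day passed") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Detected situations per day and AGGIR variable") +
    ggplot2::theme_minimal()
}

#' Timeline plot of detected activities or situations
#'
#' @param x An activity or situation tibble (columns `start`, `end` and a
#'   name column).
#' @param colour_by Column used for the segment colour (default the first of
#'   `variable`/`name`/`situation` present).
#' @return A ggplot object.
#' @export
plot_timeline <- function(x, colour_by = NULL) {
  x <- tibble::as_tibble(x)
  lab <- if ("name" %in% names(x)) "name" else "situation"
  if (is.null(colour_by)) {
    colour_by <- if ("variable" %in% names(x)) "variable" else lab
  }
  x$.y <- factor(x[[lab]], levels = rev(unique(x[[lab]])))
  ggplot2::ggplot(x, ggplot2::aes(y = .data$.y)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 3600,
                                       xend = .data$end / 3600,
                                       yend = .data$.y,
                                       colour = .data[[colour_by]]),
                          linewidth = 3) +
    ggplot2::labs(x = "hours since scenario start", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a query result series
#'
#' The graphical twin of the query layer's `series`/`value` operations.
#'
#' @param object An `adl_query_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adl_query_result
#' @export
autoplot.adl_query_result <- function(object, ...) {
  m <- object$matched
  m$value_num <- suppressWarnings(as.numeric(m$value))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$time / 3600, y = .data$value_num)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hours since scenario start", y = object$device,
                  title = sprintf("%s(%s)", object$operation, object$device)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
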