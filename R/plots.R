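# ggplot2 rendering of result objects. SVG export (export_svg) is the
# dependency-light path for sharing; these methods are for interactive use.

#' @method autoplot point_set
#' @export
autoplot.point_set <- function(object, regression = FALSE, ...) {
  state <- attr(object, "state")
  xlab <- if (is.null(state)) "x" else state$x_feature
  gcols <- attr(object, "group_id_cols")
  df <- as_tibble(object)
  if (!"y" %in% names(object)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
      ggplot2::geom_histogram(bins = sturges(nrow(df)),
                              fill = "steelblue", colour = "white") +
      ggplot2::labs(x = xlab, y = "count")
    return(p)
  }
  ylab <- if (is.null(state$y_feature)) "y" else state$y_feature
  aes <- if (length(gcols)) {
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data[[gcols[1]]])
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = xlab, y = ylab)
  if (isTRUE(regression)) {
    fit <- fit_regression(object)
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                                  linetype = "dashed")
  }
  p
}

#' @method autoplot histogram_result
#' @export
autoplot.histogram_result <- function(object, ...) {
  k <- length(object$bin_edges) - 1
  mids <- (object$bin_edges[-1] + object$bin_edges[-(k + 1)]) / 2
  df <- dplyr::bind_rows(lapply(object$series_names, function(s) {
    tibble(series = s, mid = mids, count = object$counts[[s]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge",
                      width = diff(object$bin_edges)[1] * 0.9) +
    ggplot2::labs(x = "value", y = "count")
}

#' @method autoplot density_curve
#' @export
autoplot.density_curve <- function(object, ...) {
  df <- tibble(grid = object$grid, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "value", y = "density")
}

#' @method autoplot plot_comparison
#' @export
autoplot.plot_comparison <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$mean,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "mean value")
}
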