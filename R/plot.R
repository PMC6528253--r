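# Scatter-plus-fit plots: means as points, the chosen variation as error
# bars, the fitted curve on a dense grid (log-spaced for the 4PL).

#' Plot an aggregated series with its fitted curve
#'
#' @param series A `plate_summary` (one group). Fully masked points are
#'   omitted, as they were from the fit.
#' @param fit Optional `platefit_fit` to overlay.
#' @param x_title,y_title,plot_title Axis and plot titles.
#' @return A ggplot object.
#' @export
plot_series <- function(series, fit = NULL, x_title = "Test value",
                        y_title = "Response", plot_title = NULL) {
  pts <- as_tibble(series) |>
    filter(!.data$fully_masked, !is.na(.data$mean))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$test, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$variation,
                   ymax = .data$mean + .data$variation),
      width = 0, na.rm = TRUE, colour = "grey40"
    ) +
    ggplot2::geom_point(shape = 21, size = 2.5, fill = "white") +
    ggplot2::labs(x = x_title, y = y_title, title = plot_title) +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    if (fit$model == "logistic4") {
      # log abscissa: zero-dose controls cannot be drawn there
      pts <- filter(pts, .data$test > 0)
      p <- p %+% pts + ggplot2::scale_x_log10()
    }
    grid <- curve_grid(pts$test, fit$model)
    curve <- tibble(test = grid, mean = predict(fit, grid))
    p <- p + ggplot2::geom_line(data = curve, colour = "#2166ac")
  }
  p
}

#' @importFrom ggplot2 %+%
NULL

curve_grid <- function(x, model, n = 200L) {
  if (model == "logistic4") {
    xp <- x[x > 0]
    exp(seq(log(min(xp)), log(max(xp)), length.out = n))
  } else {
    seq(min(x), max(x), length.out = n)
  }
}

#' Autoplot method for plate fits
#'
#' @param object A `platefit_fit`.
#' @param ... Passed to [plot_series()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.platefit_fit <- function(object, ...) {
  series <- tibble(
    test = object$data$x, mean = object$data$y,
    variation = NA_real_, n_used = NA_integer_, fully_masked = FALSE
  )
  plot_series(series, fit = object, ...)
}

#' Render and save a group's plot
#'
#' @param series A `plate_summary` (one group).
#' @param fit A `platefit_fit` (or NULL for points only).
#' @param config An [analysis_config()] (titles, image format).
#' @param path Output image path; extension decides nothing — the device is
#'   `config$image_format` (`"png"` or `"svg"`).
#' @return The path, invisibly.
#' @export
render_plot <- function(series, fit, config, path) {
  p <- plot_series(series, fit,
    x_title = config$x_title, y_title = config$y_title,
    plot_title = config$plot_title %||% unique(series$group)[1]
  )
  if (config$image_format == "svg") {
    grDevices::svg(path, width = 6, height = 4)
  } else {
    grDevices::png(path, width = 1200, height = 800, res = 150)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
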