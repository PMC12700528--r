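#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulated regional activity traces
#'
#' @param object a `simulation_result` (or `bold_result`).
#' @param regions region indices to draw (default up to 6).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object, regions = NULL, ...) {
  if (is.null(regions)) regions <- seq_len(min(6, nrow(object$states)))
  df <- purrr::map_dfr(regions, function(r) {
    tibble::tibble(region = factor(r), time = object$time,
                   value = object$states[r, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$region)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("time (%s)", object$time_unit),
                  y = object$model, color = "region") +
    ggplot2::theme_minimal()
}

#' Plot posterior marginals against the prior box
#'
#' @param object a `posterior_samples` object.
#' @param theta_true optional named true values drawn as vertical lines.
#' @param parameters subset of parameter names.
#' @param ... unused.
#' @return a ggplot (faceted density panels).
#' @method autoplot posterior_samples
#' @export
autoplot.posterior_samples <- function(object, theta_true = NULL,
                                       parameters = NULL, ...) {
  draws <- object$draws
  if (!is.null(parameters)) draws <- draws[, parameters, drop = FALSE]
  long <- tidyr_pivot(draws)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "firebrick", alpha = 0.4, color = "firebrick") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
  if (!is.null(theta_true)) {
    tt <- tibble::tibble(parameter = names(theta_true),
                         value = as.numeric(theta_true))
    tt <- tt[tt$parameter %in% unique(long$parameter), ]
    p <- p + ggplot2::geom_vline(data = tt,
                                 ggplot2::aes(xintercept = .data$value),
                                 color = "darkgreen", linewidth = 0.6)
  }
  p
}

# minimal long-format pivot without adding a tidyr dependency surface here
tidyr_pivot <- function(draws) {
  purrr::map_dfr(names(draws), function(nm) {
    tibble::tibble(parameter = nm, value = draws[[nm]])
  })
}

#' Shrinkage versus z-score diagnostic panel
#'
#' Reliable, accurate inference concentrates in the lower-right corner
#' (shrinkage near 1, z-score near 0).
#'
#' @param object a `diagnostics_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot diagnostics_report
#' @export
autoplot.diagnostics_report <- function(object, ...) {
  df <- tidy.diagnostics_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shrinkage, y = .data$zscore,
                                   label = .data$parameter)) +
    ggplot2::geom_point(color = "firebrick", size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "posterior shrinkage", y = "posterior z-score") +
    ggplot2::theme_minimal()
}

#' Heatmap of an FC or FCD matrix
#'
#' @param m a correlation matrix ([fc_matrix()] / [fcd_matrix()]).
#' @param title panel title.
#' @return a ggplot.
#' @export
plot_connectivity <- function(m, title = "FC") {
  m <- unclass(m)
  df <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble::tibble(row = i, col = seq_len(ncol(m)), value = m[i, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r", title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
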