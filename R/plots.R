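# ggplot2 views of fits, scans and diagnostic maps.

map_plot <- function(data, value, title, value_lab) {
  dim <- sum(coord_names(3) %in% names(data))
  if (dim == 1) {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data[[value]])) +
      ggplot2::geom_line() +
      ggplot2::labs(y = value_lab, title = title) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[value]])) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(fill = value_lab, title = title) +
      ggplot2::theme_minimal()
  }
}

#' Plot a kCSD estimate
#'
#' One time sample of the reconstructed CSD: a curve in 1D, a raster in 2D
#' (3D fits should be sliced by the caller).
#'
#' @param object A `kcsd_fit`.
#' @param time Time sample to show.
#' @param ... Unused.
#' @method autoplot kcsd_fit
#' @export
autoplot.kcsd_fit <- function(object, time = 1L, ...) {
  data <- dplyr::filter(tidy(object), .data$time == !!time)
  map_plot(data, "csd", sprintf("kCSD estimate (lambda = %.3g)",
                                object$lambda), "CSD")
}

#' Plot a parameter scan surface
#'
#' CV error or L-curve curvature over the (R, lambda) plane.
#'
#' @param object A `kcsd_scan` from [select_parameters()].
#' @param ... Unused.
#' @method autoplot kcsd_scan
#' @export
autoplot.kcsd_scan <- function(object, ...) {
  value <- if (object$method == "cv") "cv_error" else "curvature"
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$lambda, y = .data$R,
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::annotate("point", x = object$lambda, y = object$R,
                      colour = "red") +
    ggplot2::labs(title = sprintf("%s scan", object$method),
                  fill = value) +
    ggplot2::theme_minimal()
}

#' Plot the L-curve for a single basis radius
#'
#' @param model A `kcsd_model`.
#' @param V Measured potentials.
#' @param lambda_grid Ridge parameters (defaults to
#'   [default_lambda_range()]).
#' @export
plot_lcurve <- function(model, V, lambda_grid = NULL) {
  lam <- lambda_grid %||% default_lambda_range(model)$grid
  pts <- vapply(lam, function(l) lcurve_point(model, V, l), numeric(2))
  data <- tibble(lambda = lam, rho = pts["rho", ], eta = pts["eta", ])
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rho, y = .data$eta)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "prediction error rho", y = "model norm eta",
                  title = "L-curve") +
    ggplot2::theme_minimal()
}

#' Plot a measurement-uncertainty map
#'
#' @param object A `kcsd_uncertainty`.
#' @param ... Unused.
#' @method autoplot kcsd_uncertainty
#' @export
autoplot.kcsd_uncertainty <- function(object, ...) {
  map_plot(as_tibble(object), "variance", "CSD measurement uncertainty",
           "variance")
}

#' Plot a reliability map
#'
#' @param object A `kcsd_reliability`.
#' @param ... Unused.
#' @method autoplot kcsd_reliability
#' @export
autoplot.kcsd_reliability <- function(object, ...) {
  map_plot(object$mean_map, "reliability", "Reliability map",
           "mean error")
}

#' Plot broken-electrode error-increase maps
#'
#' @param object A `kcsd_broken_study`.
#' @param ... Unused.
#' @method autoplot kcsd_broken_study
#' @export
autoplot.kcsd_broken_study <- function(object, ...) {
  data <- tidy(object)
  p <- map_plot(data, "error_increase",
                "Reliability loss from broken contacts", "error increase")
  p + ggplot2::facet_wrap(~n_broken, labeller = ggplot2::label_both)
}
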