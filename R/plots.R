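route_labels <- c(
  sqrt_lm = "LM on sqrt-transformed counts",
  log_lm = "LM on log-transformed counts",
  glm = "GLM (log link)"
)

diagnostics_frame <- function(diags) {
  pts <- dplyr::bind_rows(lapply(diags, function(d) {
    dplyr::mutate(d$points, route = d$route)
  }))
  sm <- dplyr::bind_rows(lapply(diags, function(d) {
    if (nrow(d$smooth_curve) == 0) return(NULL)
    dplyr::mutate(d$smooth_curve, route = d$route)
  }))
  order <- intersect(names(route_labels), unique(pts$route))
  pts$route <- factor(pts$route, levels = order)
  if (nrow(sm) > 0) sm$route <- factor(sm$route, levels = order)
  list(points = pts, smooth = sm)
}

#' Residual-versus-fit panel for a single route
#'
#' @param object A `route_diagnostics` from [residual_diagnostics()].
#' @param ... Unused.
#' @return A ggplot: residuals against fitted values with the locally
#'   weighted smooth in red and a dashed zero line.
#' @export
autoplot.route_diagnostics <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = if (object$route == "glm") "Fitted (link scale)" else "Fitted",
      y = paste0(toupper(substring(object$residual_type, 1, 1)),
                 substring(object$residual_type, 2), " residual"),
      title = route_labels[[object$route]],
      subtitle = sprintf("fan index = %.3f", object$fan_index)
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$smooth_curve) > 0) {
    p <- p + ggplot2::geom_line(data = object$smooth_curve, colour = "red")
  }
  p
}

#' Stacked residual-versus-fit panels for the three routes
#'
#' One panel per route, stacked in route order (sqrt-LM, log-LM, GLM), each
#' with its locally weighted smooth in red — the side-by-side diagnostic view
#' on which the routes are compared.
#'
#' @param object A `route_comparison` from [compare_routes()].
#' @param ... Unused.
#' @return A ggplot with one facet per route (free scales).
#' @export
autoplot.route_comparison <- function(object, ...) {
  frames <- diagnostics_frame(object$diagnostics)
  p <- ggplot2::ggplot(frames$points,
                       ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~route, ncol = 1, scales = "free",
                        labeller = ggplot2::as_labeller(route_labels)) +
    ggplot2::labs(x = "Fitted", y = "Residual",
                  title = paste("Residual vs fit:", object$dataset_id)) +
    ggplot2::theme_minimal()
  if (nrow(frames$smooth) > 0) {
    p <- p + ggplot2::geom_line(data = frames$smooth, colour = "red")
  }
  p
}

#' Percent difference of linear-route estimates relative to the GLM
#'
#' Bar chart of the percent difference of each back-transformed linear-route
#' coefficient relative to the GLM coefficient on the count scale. Negative
#' bars indicate underestimation relative to the GLM.
#'
#' @param comparison A `route_comparison`, or the combined `pct_diff` tibbles
#'   of several comparisons.
#' @return A ggplot.
#' @export
plot_pct_diff <- function(comparison) {
  pd <- if (inherits(comparison, "route_comparison")) {
    comparison$pct_diff
  } else {
    comparison
  }
  pd <- dplyr::filter(pd, !is.na(.data$pct_diff))
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$term, y = .data$pct_diff,
                                   fill = .data$route)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Coefficient", y = "% difference vs GLM",
                  fill = "Route") +
    ggplot2::theme_minimal()
}
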