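#' Tidy a route fit
#'
#' @param x A `route_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model coefficient: `term`, `estimate`
#'   (transformed scale for the linear routes, log-link scale for the GLM),
#'   `std.error`, and `statistic` (estimate / std.error).
#' @export
tidy.route_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$coefficients / x$std_errors)
  )
}

#' One-row summary of a route fit
#'
#' @param x A `route_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `route`, `family`, `nobs`, `p.value` of the
#'   predictor term, the residual sum of squares (linear routes) or deviance
#'   (GLM) with its degrees of freedom, the negative binomial `theta` (`NA`
#'   otherwise), `converged` and `n_iter`.
#' @export
glance.route_fit <- function(x, ...) {
  tibble(
    route = x$route,
    family = x$family,
    nobs = nrow(x$data),
    p.value = x$p_value,
    deviance = x$scale_info$deviance %||% x$scale_info$rss,
    df.residual = x$scale_info$df,
    theta = x$scale_info$theta %||% NA_real_,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Tidy a three-route comparison
#'
#' @param x A `route_comparison` from [compare_routes()].
#' @param ... Unused.
#' @return A tibble with one row per route and back-transformed coefficient:
#'   `route`, `term`, `estimate` (count scale), `p.value` and `decision` of
#'   the route's predictor test, and the `pct_diff` relative to the GLM
#'   estimate (`NA` for the GLM itself).
#' @export
tidy.route_comparison <- function(x, ...) {
  decisions <- dplyr::rename(x$decisions, p.value = "p_value")
  pd <- x$pct_diff[, c("route", "term", "pct_diff")]
  x$estimates |>
    dplyr::select("route", "term", "estimate") |>
    dplyr::left_join(decisions, by = "route") |>
    dplyr::left_join(pd, by = c("route", "term"))
}

#' One-row summary of a three-route comparison
#'
#' @param x A `route_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: dataset id and kind, `alpha`, GLM `family` and
#'   Poisson `dispersion`, per-route p-values, `decisions_agree`, and the
#'   per-route fan indices.
#' @export
glance.route_comparison <- function(x, ...) {
  p <- stats::setNames(x$decisions$p_value,
                       paste0("p_", x$decisions$route))
  fans <- vapply(x$diagnostics, function(d) d$fan_index, numeric(1))
  dplyr::bind_cols(
    tibble(dataset_id = x$dataset_id, kind = x$kind, alpha = x$alpha,
           family = x$family, dispersion = x$dispersion),
    as_tibble(as.list(p)),
    tibble(decisions_agree = x$decisions_agree),
    as_tibble(as.list(stats::setNames(fans, paste0("fan_", names(fans)))))
  )
}
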