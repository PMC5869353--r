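#' Percent difference of a linear-model estimate relative to the GLM estimate
#'
#' `100 * (lm_estimate - glm_estimate) / glm_estimate`, the accuracy measure
#' used to compare back-transformed linear-model coefficients against the
#' GLM coefficients, which are taken as the reference. Undefined where the
#' GLM estimate is zero; returned as `NA` there, never as infinity.
#'
#' @param lm_estimate,glm_estimate Numeric vectors (recycled as usual).
#' @return Numeric vector of percent differences.
#' @examples
#' pct_difference(8, 10) # -20
#' @export
pct_difference <- function(lm_estimate, glm_estimate) {
  ifelse(glm_estimate == 0, NA_real_,
         100 * (lm_estimate - glm_estimate) / glm_estimate)
}

#' Residual-versus-fit diagnostics with a fan-shape index
#'
#' The diagnostic surface on which the three routes are compared: raw
#' residuals against fitted values on the transformed scale for the linear
#' routes, and deviance residuals against the link-scale fitted values for
#' the GLM, with a locally weighted regression curve (tricube weights)
#' summarizing any trend. Heteroscedasticity of the fan-shaped kind is
#' quantified by the Spearman rank correlation between absolute residuals
#' and fitted values (`fan_index`, in \[-1, 1\]; 0 when either vector is
#' constant). Smoothing requires at least 4 points; the fan index at
#' least 3.
#'
#' @param fit A `route_fit`.
#' @param span Smoother span (fraction of points in each local window,
#'   default 0.75).
#' @return A `route_diagnostics` object: `route`, `residual_type` (`"raw"` or
#'   `"deviance"`), a tibble of `(fitted, residual)` pairs, a tibble
#'   `smooth_curve` with sorted `fitted` and smoothed residuals, and
#'   `fan_index`.
#' @export
residual_diagnostics <- function(fit, span = 0.75) {
  stopifnot(inherits(fit, "route_fit"))
  is_glm <- fit$route == "glm"
  fitted <- if (is_glm) fit$eta else fit$fitted
  residual <- fit$residuals
  n <- length(residual)

  smooth_curve <- if (n >= 4) {
    sm <- lowess(fitted, residual, f = span)
    tibble(fitted = sm$x, residual = sm$y)
  } else {
    tibble(fitted = numeric(0), residual = numeric(0))
  }

  fan_index <- if (n >= 3) spearman_or_zero(abs(residual), fitted) else NA_real_

  structure(
    list(
      route = fit$route,
      residual_type = if (is_glm) "deviance" else "raw",
      points = tibble(fitted = fitted, residual = residual),
      smooth_curve = smooth_curve,
      fan_index = fan_index
    ),
    class = "route_diagnostics"
  )
}

# Spearman correlation, defined as 0 when either input is constant (zero
# variance makes the correlation undefined; a constant |residual| carries no
# fan signal).
spearman_or_zero <- function(a, b) {
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(0)
  cor(a, b, method = "spearman")
}

#' @export
print.route_diagnostics <- function(x, ...) {
  cat(sprintf("<route_diagnostics> route: %s (%s residuals), n = %d, fan index = %.3f\n",
              x$route, x$residual_type, nrow(x$points), x$fan_index))
  invisible(x)
}

#' Analyze one dataset by all three routes and compare them
#'
#' Runs the full comparison for a single count dataset: (1) linear model on
#' square-root-transformed counts, (2) linear model on log-transformed
#' counts, (3) log-link GLM with the error family chosen by the dispersion
#' rule of [choose_family()]. Each route's coefficients are returned to the
#' count scale by its back-transformation convention, decisions are taken at
#' a fixed type-I error tolerance `alpha`, percent differences of the
#' linear-route estimates relative to the GLM are computed for every
#' coefficient, and residual-versus-fit diagnostics are attached. The
#' computation is deterministic given the dataset and settings.
#'
#' @param data A count dataset (columns `y`, `x`).
#' @param alpha Type-I error tolerance for the significance decision
#'   (default 0.05); the decision is `p_value < alpha`.
#' @param sqrt_offset,log_offset Offsets of the two forward transforms
#'   (defaults 0 and 1).
#' @param log_base Base of the log transform (default `exp(1)`).
#' @param family_threshold Dispersion threshold passed to [choose_family()].
#' @param span Smoother span for [residual_diagnostics()].
#' @param theta Optional fixed negative binomial dispersion.
#' @return A `route_comparison` object: the three `route_fit`s, a tidy
#'   `decisions` table (route, p_value, decision), the combined
#'   back-transformed `estimates`, a `pct_diff` table versus the GLM (with a
#'   `glm_zero` flag where the reference is zero), per-route diagnostics,
#'   `decisions_agree`, and the family/dispersion actually used.
#' @examples
#' d <- simulate_counts(count_config("oneway", n = 20, group_means = c(2, 9)))
#' cmp <- compare_routes(d)
#' tidy(cmp)
#' @export
compare_routes <- function(data, alpha = 0.05, sqrt_offset = 0,
                           log_offset = 1, log_base = exp(1),
                           family_threshold = 1.5, span = 0.75,
                           theta = NULL) {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    abort("`alpha` must be in [0, 1).")
  }
  data <- validate_count_dataset(data)

  run_route <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Route %s failed: %s", label, conditionMessage(e)),
            parent = e)
    })
  }

  fit_sqrt <- run_route("sqrt_lm",
    fit_ols(data, transform_spec("sqrt", offset = sqrt_offset)))
  fit_log <- run_route("log_lm",
    fit_ols(data, transform_spec("log", offset = log_offset,
                                 log_base = log_base)))
  family <- run_route("glm", choose_family(data, threshold = family_threshold))
  fit_glm <- run_route("glm",
    fit_glm_irls(data, family = as.character(family), theta = theta))

  fits <- list(sqrt_lm = fit_sqrt, log_lm = fit_log, glm = fit_glm)
  estimates <- dplyr::bind_rows(lapply(fits, route_backtransform))

  decisions <- tibble(
    route = names(fits),
    p_value = vapply(fits, function(f) f$p_value, numeric(1)),
    decision = vapply(fits, function(f) f$p_value < alpha, logical(1))
  )

  glm_est <- estimates[estimates$route == "glm", c("term", "estimate")]
  names(glm_est)[2] <- "glm_estimate"
  pct_diff <- estimates |>
    dplyr::filter(.data$route != "glm") |>
    dplyr::select("route", "term", lm_estimate = "estimate") |>
    dplyr::left_join(glm_est, by = "term") |>
    dplyr::mutate(
      glm_zero = .data$glm_estimate == 0,
      pct_diff = pct_difference(.data$lm_estimate, .data$glm_estimate)
    )

  diagnostics <- lapply(fits, residual_diagnostics, span = span)

  structure(
    list(
      dataset_id = attr(data, "id", exact = TRUE) %||% "dataset",
      kind = dataset_kind(data),
      alpha = alpha,
      fits = fits,
      decisions = decisions,
      estimates = estimates,
      pct_diff = pct_diff,
      diagnostics = diagnostics,
      decisions_agree = length(unique(decisions$decision)) == 1,
      family = as.character(family),
      dispersion = attr(family, "dispersion")
    ),
    class = "route_comparison"
  )
}

#' @export
print.route_comparison <- function(x, ...) {
  cat(sprintf("<route_comparison> %s (%s), alpha = %g, GLM family: %s (dispersion %.3f)\n",
              x$dataset_id, x$kind, x$alpha, x$family, x$dispersion))
  print(as.data.frame(x$decisions), row.names = FALSE)
  cat(if (x$decisions_agree) "Decisions agree across routes.\n"
      else "Decisions DISAGREE across routes.\n")
  invisible(x)
}

#' Run the three-route comparison over a suite of datasets
#'
#' Applies [compare_routes()] to each dataset and summarizes: the number of
#' datasets in which any linear-route decision differs from the GLM decision
#' (a change of statistical decision at the fixed tolerance), and the number
#' in which the square-root route looks more fan-shaped than both other
#' routes by at least `fan_margin` on the fan index.
#'
#' @param datasets A list of count datasets (optionally named; names become
#'   dataset ids).
#' @param alpha Decision tolerance, as in [compare_routes()].
#' @param fan_margin How much larger the sqrt-route fan index must be than
#'   both other routes to count as "more fan-shaped" (default 0.1).
#' @param ... Further arguments passed to [compare_routes()].
#' @return A list with `reports` (one `route_comparison` per dataset) and
#'   `summary`, a one-row tibble with `n_datasets`, `n_decision_changes`,
#'   `n_sqrt_more_fan`, and the ids of the flagged datasets.
#' @export
run_case_suite <- function(datasets, alpha = 0.05, fan_margin = 0.1, ...) {
  if (length(datasets) < 1) abort("At least one dataset is required.")
  ids <- names(datasets) %||% sprintf("dataset%02d", seq_along(datasets))
  ids[ids == ""] <- sprintf("dataset%02d", which(ids == ""))

  reports <- purrr::map2(datasets, ids, function(d, id) {
    attr(d, "id") <- id
    compare_routes(d, alpha = alpha, ...)
  })

  changed <- vapply(reports, function(r) {
    glm_dec <- r$decisions$decision[r$decisions$route == "glm"]
    any(r$decisions$decision[r$decisions$route != "glm"] != glm_dec)
  }, logical(1))

  more_fan <- vapply(reports, function(r) {
    fans <- vapply(r$diagnostics, function(d) d$fan_index, numeric(1))
    fans[["sqrt_lm"]] > max(fans[["log_lm"]], fans[["glm"]]) + fan_margin
  }, logical(1))

  list(
    reports = reports,
    summary = tibble(
      n_datasets = length(reports),
      n_decision_changes = sum(changed),
      n_sqrt_more_fan = sum(more_fan),
      changed_ids = list(ids[changed]),
      more_fan_ids = list(ids[more_fan])
    )
  )
}
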