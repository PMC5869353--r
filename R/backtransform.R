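#' @title Back-transformation of route coefficients to the count scale
#' @description Shared helpers: transformed-scale group means under treatment
#'   coding (intercept = reference group; other groups = intercept + factor
#'   coefficient), and assembly of the tidy result.
#' @noRd
transformed_group_means <- function(fit) {
  beta <- fit$coefficients
  m <- c(beta[1], beta[1] + beta[-1])
  names(m) <- fit$levels
  m
}

original_scale_tbl <- function(fit, term, estimate, provenance) {
  out <- tibble(
    route = fit$route,
    kind = fit$kind,
    term = term,
    estimate = unname(estimate),
    provenance = provenance
  )
  class(out) <- c("original_scale", class(out))
  out
}

check_route <- function(fit, route) {
  stopifnot(inherits(fit, "route_fit"))
  if (fit$route != route) {
    abort(sprintf("Expected a %s fit, got %s.", route, fit$route))
  }
  if (fit$kind == "intercept_only") {
    abort("Back-transformation needs a fit with a predictor (oneway or regression).")
  }
}

#' Back-transform square-root-route coefficients
#'
#' Returns coefficients of the linear model on `sqrt(y + c)` to the count
#' scale by squaring. One-way designs: each transformed group mean
#' (intercept, or intercept + factor coefficient) is squared. Regressions:
#' intercept and slope are each squared. In both cases the sign of the
#' transformed value is retained after squaring, so a decreasing trend stays
#' decreasing. The forward offset `c` is *not* subtracted after squaring —
#' the reported value is `m^2`, not `m^2 - c` — which matters when `c > 0`.
#'
#' @param fit A `route_fit` with route `"sqrt_lm"`.
#' @return A tibble (`original_scale`) with columns `route`, `kind`, `term`
#'   (group level, or `"intercept"`/`"slope"`), `estimate`, `provenance`.
#' @examples
#' d <- simulate_counts(count_config("oneway", n = 10, group_means = c(2, 9)))
#' backtransform_sqrt(fit_ols(d, transform_spec("sqrt")))
#' @export
backtransform_sqrt <- function(fit) {
  check_route(fit, "sqrt_lm")
  prov <- sprintf("square, sign retained; offset c=%g not subtracted",
                  fit$spec$offset)
  if (fit$kind == "oneway") {
    m <- transformed_group_means(fit)
    original_scale_tbl(fit, names(m), sign(m) * m^2, prov)
  } else {
    b <- fit$coefficients
    original_scale_tbl(fit, c("intercept", "slope"), sign(b) * b^2, prov)
  }
}

#' Back-transform log-route coefficients
#'
#' Returns coefficients of the linear model on `log(y + c)` to the count
#' scale as `base^m - 1`: each transformed group mean (one-way) or each of
#' the intercept and slope (regression) is exponentiated in the base used by
#' the forward transform, and 1 is subtracted. For a one-way design this
#' yields (shifted) geometric means. Note the convention subtracts 1
#' regardless of the forward offset `c`; with the usual `log(y + 1)` the two
#' coincide, but the subtraction is a fixed convention, not the arithmetic
#' inverse of the transform (see [invert_transform()] for that).
#'
#' @param fit A `route_fit` with route `"log_lm"`.
#' @param spec The [transform_spec()] used in the forward direction; defaults
#'   to the one stored in the fit, so the same base is always used.
#' @return A tibble as in [backtransform_sqrt()].
#' @export
backtransform_log <- function(fit, spec = fit$spec) {
  check_route(fit, "log_lm")
  base <- spec$log_base
  base_lab <- if (isTRUE(all.equal(base, 10))) "10" else "e"
  prov <- sprintf("%s^m - 1 (forward offset c=%g)", base_lab, spec$offset)
  if (fit$kind == "oneway") {
    m <- transformed_group_means(fit)
    original_scale_tbl(fit, names(m), base^m - 1, prov)
  } else {
    b <- fit$coefficients
    original_scale_tbl(fit, c("intercept", "slope"), base^b - 1, prov)
  }
}

#' Back-transform GLM coefficients
#'
#' Log-link GLM coefficients are multiplicative: the exponentiated factor
#' coefficient is the proportion relative to the reference mean. One-way
#' designs: the group mean is the exponentiated intercept multiplied by the
#' exponentiated factor coefficient, `exp(b0) * exp(b_level) =
#' exp(b0 + b_level)` (reference group: `exp(b0)`). Regressions: the
#' intercept is `exp(b0)` and the slope is reported as the per-unit
#' proportional change minus one, `exp(b1) - 1`.
#'
#' @param fit A `route_fit` with route `"glm"`.
#' @return A tibble as in [backtransform_sqrt()]; one-way group means are
#'   always positive.
#' @export
backtransform_glm <- function(fit) {
  check_route(fit, "glm")
  if (fit$kind == "oneway") {
    m <- transformed_group_means(fit)
    original_scale_tbl(fit, names(m), exp(m),
                       "exp(b0) * exp(b_level) group means")
  } else {
    b <- fit$coefficients
    original_scale_tbl(
      fit, c("intercept", "slope"), c(exp(b[1]), exp(b[2]) - 1),
      "intercept exp(b0); slope exp(b1) - 1 (proportion change minus one)"
    )
  }
}

# Dispatch on the route stored in the fit.
route_backtransform <- function(fit) {
  switch(fit$route,
    sqrt_lm = backtransform_sqrt(fit),
    log_lm = backtransform_log(fit),
    glm = backtransform_glm(fit),
    abort(sprintf("Unknown route '%s'.", fit$route))
  )
}
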