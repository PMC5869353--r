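#' @title Fitting routes for count data
#' @description Internal construction of the design matrix shared by all
#'   routes. Treatment coding with the alphabetically first level as
#'   reference, matching the convention under which a factor coefficient is
#'   "added to the value of the intercept" to give a group mean.
#' @noRd
build_design <- function(data, kind) {
  if (kind == "regression") {
    x <- as.numeric(data$x)
    X <- cbind("(Intercept)" = rep(1, nrow(data)), x = x)
    levels <- NULL
  } else {
    f <- factor(data$x)
    X <- model.matrix(~f, data = data.frame(f = f))
    colnames(X) <- c("(Intercept)", levels(f)[-1])
    levels <- levels(f)
  }
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient (constant covariate or aliased groups).")
  }
  list(X = X, levels = levels)
}

new_route_fit <- function(route, family, coefficients, std_errors, fitted,
                          residuals, scale_info, p_value, converged, n_iter,
                          data, kind, levels = NULL, spec = NULL, eta = NULL) {
  structure(
    list(
      route = route, family = family, coefficients = coefficients,
      std_errors = std_errors, fitted = fitted, residuals = residuals,
      scale_info = scale_info, p_value = p_value, converged = converged,
      n_iter = n_iter, data = data, kind = kind, levels = levels,
      spec = spec, eta = eta
    ),
    class = "route_fit"
  )
}

#' @export
print.route_fit <- function(x, ...) {
  cat(sprintf("<route_fit> route: %s  family: %s  n: %d\n",
              x$route, x$family, nrow(x$data)))
  print(round(x$coefficients, 5))
  cat(sprintf("predictor p-value: %.5g\n", x$p_value))
  invisible(x)
}

#' Fit an ordinary linear model to transformed counts
#'
#' Routes 1 and 2 of the comparison: transform the response with
#' [apply_transform()] and fit a Gaussian linear model of the transformed
#' response on the single predictor. The predictor-term p-value is the
#' overall F test of the model against the intercept-only model. Fitted
#' values and residuals are on the transformed scale.
#'
#' @param data A count dataset (data frame with columns `y`, `x`).
#' @param spec A [transform_spec()]; `sqrt` yields route `"sqrt_lm"`, `log`
#'   route `"log_lm"`.
#' @return A `route_fit` object: coefficients on the transformed scale with
#'   standard errors, fitted values, raw residuals, residual sum of squares
#'   and degrees of freedom, and the F-test p-value.
#' @examples
#' d <- simulate_counts(count_config("oneway", n = 10, group_means = c(2, 9)))
#' fit_ols(d, transform_spec("sqrt"))
#' @export
fit_ols <- function(data, spec = transform_spec("sqrt")) {
  data <- validate_count_dataset(data)
  kind <- dataset_kind(data)
  z <- apply_transform(data$y, spec)
  des <- build_design(data, kind)

  df <- data.frame(z = z, data[, "x", drop = FALSE])
  fit <- lm(z ~ x, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_value <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))

  beta <- stats::coef(fit)
  names(beta) <- colnames(des$X)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- colnames(des$X)

  new_route_fit(
    route = if (spec$name == "sqrt") "sqrt_lm" else "log_lm",
    family = "gaussian",
    coefficients = beta,
    std_errors = se,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    scale_info = list(rss = sum(stats::residuals(fit)^2),
                      df = fit$df.residual),
    p_value = p_value,
    converged = TRUE,
    n_iter = 1L,
    data = data, kind = kind, levels = des$levels, spec = spec
  )
}

# Log-likelihoods on the count scale ----------------------------------------

poisson_loglik <- function(y, mu) sum(stats::dpois(y, mu, log = TRUE))

negbin_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

glm_deviance <- function(y, mu, family, theta = NULL) {
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  if (family == "poisson") {
    2 * sum(ylogy - (y - mu))
  } else {
    2 * sum(ylogy - (y + theta) * log((y + theta) / (mu + theta)))
  }
}

deviance_residuals <- function(y, mu, family, theta = NULL) {
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  d <- if (family == "poisson") {
    2 * (ylogy - (y - mu))
  } else {
    2 * (ylogy - (y + theta) * log((y + theta) / (mu + theta)))
  }
  sign(y - mu) * sqrt(pmax(d, 0))
}

# One IRLS solve at fixed family/theta. Working response
# z = eta + (y - mu)/mu, weights mu (Poisson) or mu/(1 + mu/theta) (NB);
# initialization mu = y + 0.5 guards log(0).
irls_solve <- function(X, y, family, theta = NULL, tol = 1e-8,
                       max_iter = 100L) {
  mu <- y + 0.5
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    w <- if (family == "poisson") mu else mu / (1 + mu / theta)
    z <- eta + (y - mu) / mu
    wls <- stats::lm.wfit(X, z, w)
    beta_new <- wls$coefficients
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  w <- if (family == "poisson") mu else mu / (1 + mu / theta)
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  names(se) <- colnames(X)
  names(beta) <- colnames(X)
  loglik <- if (family == "poisson") poisson_loglik(y, mu) else
    negbin_loglik(y, mu, theta)
  list(beta = beta, se = se, mu = mu, eta = eta,
       deviance = glm_deviance(y, mu, family, theta),
       loglik = loglik, n_iter = iter, converged = converged, trace = trace)
}

# Alternate IRLS(beta | theta) with one-dimensional maximization of the NB
# log-likelihood in log(theta) over [-7, 12]; stop when the log-likelihood
# improves by less than tol_ll.
estimate_theta <- function(X, y, tol = 1e-8, max_iter = 100L,
                           tol_ll = 1e-8, max_outer = 50L) {
  m <- mean(y)
  v <- stats::var(y)
  theta <- if (is.finite(v) && v > m) m^2 / (v - m) else 10
  theta <- min(max(theta, exp(-7)), exp(12))
  ll_old <- -Inf
  fit <- NULL
  for (outer in seq_len(max_outer)) {
    fit <- irls_solve(X, y, "negbin", theta = theta, tol = tol,
                      max_iter = max_iter)
    opt <- optimize(
      function(lt) negbin_loglik(y, fit$mu, exp(lt)),
      interval = c(-7, 12), maximum = TRUE, tol = 1e-10
    )
    theta <- exp(opt$maximum)
    ll_new <- opt$objective
    if (abs(ll_new - ll_old) < tol_ll) break
    ll_old <- ll_new
  }
  if (!fit$converged) {
    abort("Negative binomial theta estimation did not converge.",
          class = "countroutes_theta_error")
  }
  list(theta = theta, fit = irls_solve(X, y, "negbin", theta = theta,
                                       tol = tol, max_iter = max_iter))
}

#' Fit a log-link GLM to counts by iteratively reweighted least squares
#'
#' Route 3 of the comparison. Poisson or negative binomial errors with a log
#' link, fitted by IRLS: working response `z = eta + (y - mu)/mu`, weights
#' `mu` (Poisson) or `mu / (1 + mu/theta)` (negative binomial), convergence
#' when the largest coefficient change falls below `tol`. When
#' `family = "negbin"` and `theta` is not supplied, theta (the dispersion
#' parameter of the variance function `mu + mu^2/theta`) is estimated by
#' alternating IRLS in the coefficients with one-dimensional maximization of
#' the negative binomial log-likelihood in `log(theta)`. The predictor-term
#' p-value is the likelihood-ratio (analysis of deviance) chi-square test
#' against the intercept-only model, with theta held at the full-model
#' estimate for both fits.
#'
#' @param data A count dataset (columns `y` and `x`); if `x` is absent an
#'   intercept-only model is fitted and no predictor test is reported.
#' @param family `"poisson"` or `"negbin"`.
#' @param theta Optional fixed dispersion for `"negbin"`; estimated when
#'   `NULL`.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A `route_fit`: coefficients on the log-link scale with standard
#'   errors, fitted means on the count scale, deviance residuals, deviance
#'   and residual degrees of freedom (plus the theta estimate for the
#'   negative binomial), and the likelihood-ratio p-value.
#' @examples
#' d <- simulate_counts(count_config("oneway", n = 10, group_means = c(2, 9)))
#' fit_glm_irls(d, family = "poisson")
#' @export
fit_glm_irls <- function(data, family = c("poisson", "negbin"), theta = NULL,
                         tol = 1e-8, max_iter = 100L) {
  family <- match.arg(family)
  intercept_only <- !("x" %in% names(data))

  if (intercept_only) {
    y <- data$y
    if (any(!is.finite(y) | y < 0 | y != round(y))) {
      abort("Response must be non-negative integers.")
    }
    data <- as_tibble(data)
    kind <- "intercept_only"
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
    levels <- NULL
  } else {
    data <- validate_count_dataset(data)
    kind <- dataset_kind(data)
    y <- data$y
    des <- build_design(data, kind)
    X <- des$X
    levels <- des$levels
  }
  if (all(y == 0)) {
    abort("All-zero response: a log-link GLM mean cannot be estimated.")
  }

  if (family == "negbin" && is.null(theta)) {
    est <- estimate_theta(X, y, tol = tol, max_iter = max_iter)
    theta <- est$theta
    full <- est$fit
  } else {
    full <- irls_solve(X, y, family, theta = theta, tol = tol,
                       max_iter = max_iter)
  }
  if (!full$converged) {
    abort(sprintf(
      "IRLS did not converge in %d iterations (last max |delta beta| = %.3g; trace: %s).",
      max_iter, utils::tail(full$trace, 1),
      paste(signif(utils::tail(full$trace, 5), 3), collapse = ", ")
    ))
  }

  if (intercept_only) {
    p_value <- NA_real_
  } else {
    X0 <- X[, 1, drop = FALSE]
    null <- irls_solve(X0, y, family, theta = theta, tol = tol,
                       max_iter = max_iter)
    lr <- 2 * (full$loglik - null$loglik)
    p_value <- pchisq(max(lr, 0), df = ncol(X) - 1, lower.tail = FALSE)
  }

  scale_info <- list(deviance = full$deviance,
                     df = length(y) - ncol(X))
  if (family == "negbin") scale_info$theta <- theta

  new_route_fit(
    route = "glm", family = family,
    coefficients = full$beta, std_errors = full$se,
    fitted = full$mu,
    residuals = deviance_residuals(y, full$mu, family, theta),
    scale_info = scale_info,
    p_value = p_value, converged = full$converged, n_iter = full$n_iter,
    data = data, kind = kind, levels = levels, eta = full$eta
  )
}

#' Pearson dispersion statistic of a Poisson fit
#'
#' Pearson chi-square divided by the residual degrees of freedom,
#' `sum((y - mu)^2 / mu) / (n - p)`. Values near 1 indicate equidispersion;
#' under a negative binomial truth the expectation is roughly
#' `1 + mu/theta`.
#'
#' @param fit A Poisson `route_fit` from [fit_glm_irls()].
#' @param data Optional dataset; defaults to the data stored in the fit.
#' @return The dispersion statistic (a single number).
#' @export
dispersion_statistic <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "route_fit"))
  if (fit$route != "glm" || fit$family != "poisson") {
    abort("Dispersion statistic is defined for Poisson GLM fits.")
  }
  y <- (data %||% fit$data)$y
  mu <- fit$fitted
  if (any(mu == 0)) abort("Fitted mean of zero; dispersion undefined.")
  df <- length(y) - length(fit$coefficients)
  sum((y - mu)^2 / mu) / df
}

#' Choose the GLM error family from the dispersion statistic
#'
#' Fits a Poisson GLM and computes [dispersion_statistic()]; returns
#' `"negbin"` when the statistic exceeds `threshold`, `"poisson"` otherwise.
#' This automates the visual residual-plot judgement of over-dispersion with
#' a reproducible rule; the statistic is attached to the result so it can
#' always be reported.
#'
#' @param data A count dataset.
#' @param threshold Dispersion value above which the negative binomial is
#'   selected (default 1.5); `Inf` always selects Poisson.
#' @return `"poisson"` or `"negbin"`, with the Poisson dispersion statistic
#'   in `attr(, "dispersion")`.
#' @export
choose_family <- function(data, threshold = 1.5) {
  fit <- fit_glm_irls(data, family = "poisson")
  disp <- dispersion_statistic(fit)
  out <- if (disp > threshold) "negbin" else "poisson"
  attr(out, "dispersion") <- disp
  out
}
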