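`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: direct maximization of the GLM log-likelihood by
# quasi-Newton with analytic gradient, never via IRLS.
oracle_glm_optim <- function(X, y, family = "poisson", theta = NULL) {
  negll <- function(beta) {
    mu <- exp(drop(X %*% beta))
    if (family == "poisson") {
      -sum(stats::dpois(y, mu, log = TRUE))
    } else {
      -sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
             theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
    }
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta))
    r <- if (family == "poisson") y - mu else (y - mu) * theta / (theta + mu)
    -drop(crossprod(X, r))
  }
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  opt$par
}

# Design matrix in the package's parameterization, built independently.
oracle_design <- function(data) {
  if (is.numeric(data$x)) {
    cbind(1, data$x)
  } else {
    stats::model.matrix(~factor(data$x), data = data)
  }
}

# Dataset constructors used across test files.
make_oneway <- function(..., labels = NULL) {
  groups <- list(...)
  labels <- labels %||% sprintf("g%d", seq_along(groups))
  tibble::tibble(
    y = as.integer(unlist(groups)),
    x = factor(rep(labels, lengths(groups)), levels = sort(labels))
  )
}

make_regression <- function(y, x) {
  tibble::tibble(y = as.integer(y), x = as.numeric(x))
}

# A route_fit skeleton with prescribed coefficients, for checking the
# back-transformation formulas in isolation from fitting.
fake_fit <- function(route, kind, coefficients, levels = NULL, spec = NULL,
                     n = 6) {
  if (is.null(spec) && route == "sqrt_lm") spec <- transform_spec("sqrt")
  if (is.null(spec) && route == "log_lm") spec <- transform_spec("log")
  structure(
    list(
      route = route,
      family = if (route == "glm") "poisson" else "gaussian",
      coefficients = coefficients,
      std_errors = rep(1, length(coefficients)),
      fitted = rep(1, n), residuals = rep(0, n), eta = rep(0, n),
      scale_info = list(), p_value = 0.5, converged = TRUE, n_iter = 1L,
      data = tibble::tibble(y = rep(1L, n), x = rep(c("a", "b"), length.out = n)),
      kind = kind, levels = levels, spec = spec
    ),
    class = "route_fit"
  )
}
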