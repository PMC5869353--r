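#' Configuration for the synthetic count-data generator
#'
#' Describes a generative scenario with known ground truth: a one-way
#' categorical design with fixed group means, or a single-covariate log-linear
#' regression with coefficients on the log-link scale. The configuration is
#' echoed into every dataset it generates so recovery studies can compare
#' estimates against truth.
#'
#' @param design `"oneway"` (counts in `length(group_means)` groups) or
#'   `"regression"` (counts along a single continuous covariate).
#' @param n Observations per group (`oneway`) or in total (`regression`).
#'   Must be at least 2.
#' @param group_means Positive group means on the count scale (`oneway` only;
#'   at least two groups).
#' @param beta Length-2 numeric `(beta0, beta1)` on the log-link scale
#'   (`regression` only): the mean at covariate value `x` is
#'   `exp(beta0 + beta1 * x)`.
#' @param covariate_range Length-2 interval over which the regression
#'   covariate is evenly spaced. The default, 0 to 10, mirrors count series
#'   indexed by time over roughly a decade.
#' @param family Sampling distribution: `"poisson"` (variance equal to the
#'   mean) or `"negbin"` (variance `mu + mu^2 / theta`).
#' @param theta Positive dispersion parameter, required when
#'   `family = "negbin"`. Larger `theta` approaches the Poisson.
#' @param seed Integer seed; the same configuration always reproduces the
#'   same dataset.
#'
#' @return A `count_config` object (a validated list of the above fields).
#' @seealso [simulate_counts()], [simulate_null()]
#' @examples
#' count_config("oneway", n = 10, group_means = c(2, 8), seed = 1)
#' count_config("regression", n = 20, beta = c(1, 0.3), seed = 1)
#' @export
count_config <- function(design = c("oneway", "regression"),
                         n = 30,
                         group_means = NULL,
                         beta = NULL,
                         covariate_range = c(0, 10),
                         family = c("poisson", "negbin"),
                         theta = NULL,
                         seed = 1L) {
  design <- match.arg(design)
  family <- match.arg(family)

  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.")
  }
  n <- as.integer(n)

  if (design == "oneway") {
    if (is.null(group_means) || length(group_means) < 2) {
      abort("A one-way design needs `group_means` with at least two groups.")
    }
    if (any(!is.finite(group_means)) || any(group_means <= 0)) {
      abort("All `group_means` must be finite and > 0 (counts have positive means).")
    }
    beta <- NULL
  } else {
    if (is.null(beta) || length(beta) != 2 || any(!is.finite(beta))) {
      abort("A regression design needs `beta = c(beta0, beta1)` on the log-link scale.")
    }
    if (length(covariate_range) != 2 || !is.numeric(covariate_range) ||
        covariate_range[1] >= covariate_range[2]) {
      abort("`covariate_range` must be an increasing length-2 interval.")
    }
    group_means <- NULL
  }

  if (family == "negbin") {
    if (is.null(theta) || !is.finite(theta) || theta <= 0) {
      abort("`family = \"negbin\"` requires a finite `theta` > 0.")
    }
  } else {
    theta <- NULL
  }

  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    abort("`seed` must be a single integer.")
  }

  structure(
    list(
      design = design, n = n, group_means = group_means, beta = beta,
      covariate_range = covariate_range, family = family, theta = theta,
      seed = as.integer(seed)
    ),
    class = "count_config"
  )
}

#' @export
print.count_config <- function(x, ...) {
  cat("<count_config>\n")
  cat("  design:", x$design, " family:", x$family, " n:", x$n, "\n")
  if (x$design == "oneway") {
    cat("  group means:", paste(signif(x$group_means, 4), collapse = ", "), "\n")
  } else {
    cat("  beta (log link):", paste(signif(x$beta, 4), collapse = ", "),
        " covariate range:", paste(x$covariate_range, collapse = " .. "), "\n")
  }
  if (!is.null(x$theta)) cat("  theta:", x$theta, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Replace a scenario by its null counterpart: equal group means (their
# arithmetic mean, preserving total expected count) or zero slope.
nullify_config <- function(config) {
  stopifnot(inherits(config, "count_config"))
  if (config$design == "oneway") {
    config$group_means <- rep(mean(config$group_means), length(config$group_means))
  } else {
    config$beta[2] <- 0
  }
  config
}
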