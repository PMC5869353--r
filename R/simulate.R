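#' Generate a synthetic count dataset with known truth
#'
#' Draws counts from the configured scenario: per-group Poisson or negative
#' binomial counts under a one-way design, or counts whose log mean is linear
#' in a covariate evenly spaced over `covariate_range`. The covariate is
#' deterministic so parameter-recovery studies are not confounded by design
#' randomness. Zeros arise naturally at small means; there is no zero
#' inflation mechanism.
#'
#' @param config A [count_config()].
#' @param seed Optional integer overriding `config$seed`.
#'
#' @return A tibble with columns `y` (integer counts) and `x` (factor of group
#'   labels, or numeric covariate), carrying attributes `kind`
#'   (`"oneway"`/`"regression"`), `truth` (the generating configuration) and
#'   `id` (a text label).
#' @examples
#' cfg <- count_config("oneway", n = 5, group_means = c(2, 8), seed = 42)
#' simulate_counts(cfg)
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "count_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)

  withr::with_seed(config$seed, {
    if (config$design == "oneway") {
      k <- length(config$group_means)
      labels <- sprintf("g%d", seq_len(k))
      x <- factor(rep(labels, each = config$n), levels = labels)
      mu <- rep(config$group_means, each = config$n)
    } else {
      x <- seq(config$covariate_range[1], config$covariate_range[2],
               length.out = config$n)
      mu <- exp(config$beta[1] + config$beta[2] * x)
    }
    y <- if (config$family == "poisson") {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = config$theta)
    }
  })

  new_count_dataset(
    tibble(y = as.integer(y), x = x),
    kind = config$design,
    truth = config,
    id = sprintf("%s-%s-seed%d", config$design, config$family, config$seed)
  )
}

#' Generate a dataset under the null hypothesis
#'
#' Identical to [simulate_counts()] except that the scenario is first replaced
#' by its null counterpart: all group means set equal (to the arithmetic mean
#' of the configured means, preserving the total expected count) for a one-way
#' design, or the slope forced to zero for a regression. The echoed `truth`
#' attribute records the null configuration. Used by type-I error studies.
#'
#' @inheritParams simulate_counts
#' @return A tibble as in [simulate_counts()]; `attr(., "truth")` is the null
#'   configuration.
#' @examples
#' cfg <- count_config("oneway", n = 5, group_means = c(3, 7), seed = 1)
#' attr(simulate_null(cfg), "truth")$group_means
#' @export
simulate_null <- function(config, seed = NULL) {
  simulate_counts(nullify_config(config), seed = seed)
}

new_count_dataset <- function(data, kind, truth = NULL, id = "dataset") {
  out <- as_tibble(data)
  attr(out, "kind") <- kind
  attr(out, "truth") <- truth
  attr(out, "id") <- id
  out
}

#' Validate a count dataset and infer its design kind
#'
#' A valid dataset is a data frame with a non-negative integer response `y`
#' and a single explanatory column `x`, either categorical (factor/character,
#' at least two levels each with one observation: a one-way design) or
#' numeric (a regression design).
#'
#' @param data A data frame with columns `y` and `x`.
#' @return The dataset as a tibble with a `kind` attribute set; errors
#'   describe the first violated constraint.
#' @export
validate_count_dataset <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!all(c("y", "x") %in% names(data))) {
    abort("`data` must have columns `y` (counts) and `x` (predictor).")
  }
  y <- data$y
  if (length(y) < 2) abort("At least two observations are required.")
  bad <- which(!is.finite(y) | y < 0 | y != round(y))
  if (length(bad) > 0) {
    abort(sprintf(
      "Response must be non-negative integers; offending row(s): %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  kind <- dataset_kind(data)
  if (kind == "oneway") {
    f <- factor(data$x)
    if (nlevels(f) < 2) abort("A one-way design needs at least two groups.")
  }
  out <- as_tibble(data)
  out$y <- as.integer(out$y)
  attr(out, "kind") <- kind
  attr(out, "truth") <- attr(data, "truth", exact = TRUE)
  attr(out, "id") <- attr(data, "id", exact = TRUE) %||% "dataset"
  out
}

dataset_kind <- function(data) {
  k <- attr(data, "kind", exact = TRUE)
  if (!is.null(k)) return(k)
  if (is.numeric(data$x)) "regression" else "oneway"
}
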