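# Fit all three routes on one replicate, returning p-values.
# Negative binomial theta-estimation failures fall back to a Poisson fit and
# are flagged, so rejection-rate denominators stay honest.
replicate_routes <- function(data, family_threshold = 1.5) {
  fit_sqrt <- fit_ols(data, transform_spec("sqrt"))
  fit_log <- fit_ols(data, transform_spec("log"))
  family <- choose_family(data, threshold = family_threshold)
  fallback <- FALSE
  fit_glm <- tryCatch(
    fit_glm_irls(data, family = as.character(family)),
    countroutes_theta_error = function(e) {
      fallback <<- TRUE
      fit_glm_irls(data, family = "poisson")
    }
  )
  list(fits = list(sqrt_lm = fit_sqrt, log_lm = fit_log, glm = fit_glm),
       fallback = fallback)
}

ROUTES <- c("sqrt_lm", "log_lm", "glm")

#' Monte-Carlo type-I error study of the three routes
#'
#' Repeatedly generates data under the null version of a scenario (equal
#' group means, or zero slope), analyzes each replicate by all three routes,
#' and records the rejection rate of the predictor-term test at tolerance
#' `alpha`. Replicate `r` uses seed `seed + r`, so the study is reproducible
#' and parallelizable without shared state. Replicates whose fitting fails
#' are counted and reported, never silently dropped; the study errors if
#' more than 5\% fail.
#'
#' @param config A [count_config()] scenario; its null counterpart is
#'   generated internally, so a non-null configuration may be supplied.
#' @param n_reps Number of Monte-Carlo replicates (at least 100).
#' @param alpha Decision tolerance (default 0.05; rejection is
#'   `p_value < alpha`).
#' @param seed Master seed for the replicate-seed scheme.
#' @param family_threshold Dispersion threshold for GLM family choice.
#' @return A tibble with one row per route: `rejection_rate`, its Monte-Carlo
#'   standard error `mc_se = sqrt(r(1-r)/n)`, `n_reps`, `n_fail`, and
#'   `n_fallback` (negative binomial fits that fell back to Poisson). The
#'   null configuration is attached as attribute `scenario`.
#' @examples
#' cfg <- count_config("oneway", n = 10, group_means = c(5, 5))
#' type1_error_study(cfg, n_reps = 100, seed = 7)
#' @export
type1_error_study <- function(config, n_reps, alpha = 0.05, seed = 1L,
                              family_threshold = 1.5) {
  stopifnot(inherits(config, "count_config"))
  if (n_reps < 100) abort("`n_reps` must be at least 100.")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    abort("`alpha` must be in [0, 1).")
  }
  null_cfg <- nullify_config(config)

  reject <- matrix(NA, nrow = n_reps, ncol = 3,
                   dimnames = list(NULL, ROUTES))
  n_fail <- 0L
  n_fallback <- 0L
  for (r in seq_len(n_reps)) {
    data <- simulate_counts(null_cfg, seed = seed + r)
    rep_fit <- tryCatch(replicate_routes(data, family_threshold),
                        error = function(e) NULL)
    if (is.null(rep_fit)) {
      n_fail <- n_fail + 1L
      next
    }
    if (rep_fit$fallback) n_fallback <- n_fallback + 1L
    reject[r, ] <- vapply(rep_fit$fits[ROUTES],
                          function(f) f$p_value < alpha, logical(1))
  }
  if (n_fail > 0.05 * n_reps) {
    abort(sprintf("%d of %d replicates failed to fit (> 5%%).",
                  n_fail, n_reps))
  }

  n_ok <- n_reps - n_fail
  rate <- colMeans(reject, na.rm = TRUE)
  out <- tibble(
    route = ROUTES,
    rejection_rate = unname(rate),
    mc_se = sqrt(unname(rate) * (1 - unname(rate)) / n_ok),
    n_reps = n_ok,
    n_fail = n_fail,
    n_fallback = n_fallback
  )
  attr(out, "scenario") <- null_cfg
  attr(out, "alpha") <- alpha
  out
}

# Truth on the count scale: group means, or (exp(b0), exp(b1) - 1) -- the
# quantities the GLM back-transformation targets.
truth_count_scale <- function(config) {
  if (config$design == "oneway") {
    stats::setNames(config$group_means,
                    sprintf("g%d", seq_along(config$group_means)))
  } else {
    c(intercept = exp(config$beta[1]), slope = exp(config$beta[2]) - 1)
  }
}

# Truth on the log-link scale, in the design-matrix parameterization.
truth_link_scale <- function(config) {
  if (config$design == "oneway") {
    m <- config$group_means
    stats::setNames(c(log(m[1]), log(m[-1] / m[1])),
                    c("(Intercept)", sprintf("g%d", seq_along(m)[-1])))
  } else {
    stats::setNames(config$beta, c("(Intercept)", "x"))
  }
}

#' Monte-Carlo coefficient-recovery study of the three routes
#'
#' Repeatedly generates data from a non-null scenario with known truth,
#' back-transforms each route's coefficients to the count scale, and
#' summarizes their bias and root-mean-square error against the generating
#' values (group means for one-way designs; `exp(b0)` and `exp(b1) - 1` for
#' regressions). For the GLM route the study additionally tracks the
#' link-scale coefficients and the coverage of their 95\% Wald intervals.
#' Replicate `r` uses seed `seed + r`.
#'
#' @inheritParams type1_error_study
#' @param n_reps Number of replicates (any positive integer; with
#'   `n_reps = 1` the bias equals the single replicate's error exactly).
#' @return A tibble with one row per route x coefficient x scale:
#'   `route`, `term`, `scale` (`"count"`, or `"link"` for the GLM Wald
#'   summary), `truth`, `mean_estimate`, `bias`, `rmse`, `coverage` (link
#'   scale only), `n_reps`, `n_fail`, `n_fallback`. Pivot with
#'   [study_long()] for a fully long table.
#' @examples
#' cfg <- count_config("oneway", n = 20, group_means = c(5, 15))
#' recovery_study(cfg, n_reps = 50, seed = 3)
#' @export
recovery_study <- function(config, n_reps, seed = 1L,
                           family_threshold = 1.5) {
  stopifnot(inherits(config, "count_config"))
  if (n_reps < 1) abort("`n_reps` must be positive.")
  is_null_scenario <- if (config$design == "oneway") {
    length(unique(config$group_means)) == 1
  } else {
    config$beta[2] == 0
  }
  if (is_null_scenario) {
    abort("Recovery requires a non-null scenario (an effect to recover).")
  }

  truth_count <- truth_count_scale(config)
  truth_link <- truth_link_scale(config)
  z975 <- qnorm(0.975)

  count_rows <- list()
  link_rows <- list()
  n_fail <- 0L
  n_fallback <- 0L
  for (r in seq_len(n_reps)) {
    data <- simulate_counts(config, seed = seed + r)
    rep_fit <- tryCatch(replicate_routes(data, family_threshold),
                        error = function(e) NULL)
    if (is.null(rep_fit)) {
      n_fail <- n_fail + 1L
      next
    }
    if (rep_fit$fallback) n_fallback <- n_fallback + 1L
    count_rows[[length(count_rows) + 1L]] <-
      dplyr::bind_rows(lapply(rep_fit$fits, route_backtransform))[
        , c("route", "term", "estimate")]
    g <- rep_fit$fits$glm
    link_rows[[length(link_rows) + 1L]] <- tibble(
      term = names(g$coefficients),
      estimate = unname(g$coefficients),
      covered = abs(unname(g$coefficients) - unname(truth_link)) <=
        z975 * unname(g$std_errors)
    )
  }
  if (n_fail > 0.05 * n_reps) {
    abort(sprintf("%d of %d replicates failed to fit (> 5%%).",
                  n_fail, n_reps))
  }

  truth_tbl <- tibble(term = names(truth_count),
                      truth = unname(truth_count))
  count_summary <- dplyr::bind_rows(count_rows) |>
    dplyr::left_join(truth_tbl, by = "term") |>
    dplyr::group_by(.data$route, .data$term) |>
    dplyr::summarise(
      scale = "count",
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = NA_real_,
      .groups = "drop"
    )

  link_truth_tbl <- tibble(term = names(truth_link),
                           truth = unname(truth_link))
  link_summary <- dplyr::bind_rows(link_rows) |>
    dplyr::left_join(link_truth_tbl, by = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      route = "glm",
      scale = "link",
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      .groups = "drop"
    )

  out <- dplyr::bind_rows(count_summary, link_summary) |>
    dplyr::select("route", "term", "scale", "truth", "mean_estimate",
                  "bias", "rmse", "coverage") |>
    dplyr::mutate(n_reps = n_reps - n_fail, n_fail = n_fail,
                  n_fallback = n_fallback)
  attr(out, "scenario") <- config
  out
}

#' Pivot a study summary to fully long format
#'
#' Reshapes the output of [type1_error_study()] or [recovery_study()] into a
#' `(route, term, scale, metric, value)` table convenient for plotting and
#' concatenating across scenarios.
#'
#' @param summary A study summary tibble.
#' @return A long tibble with columns `route`, (`term`, `scale` if present),
#'   `metric`, `value`.
#' @export
study_long <- function(summary) {
  id_cols <- intersect(c("route", "term", "scale"), names(summary))
  summary |>
    dplyr::select(-dplyr::any_of(c("n_reps", "n_fail", "n_fallback"))) |>
    tidyr::pivot_longer(-dplyr::all_of(id_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}
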