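test_that("percent difference is relative to the GLM estimate, NA at zero", {
  expect_equal(pct_difference(8, 10), -20)
  expect_equal(pct_difference(10, 10), 0)
  expect_equal(pct_difference(15, 10), 50)
  expect_true(is.na(pct_difference(3, 0)))
  expect_equal(pct_difference(c(8, 15), c(10, 10)), c(-20, 50))
})

test_that("fan index captures the residual-spread pattern", {
  # constant |residual|, alternating sign: no fan
  f <- fake_fit("sqrt_lm", "oneway", c("(Intercept)" = 1, g2 = 0),
                levels = c("g1", "g2"), n = 8)
  f$fitted <- 1:8
  f$residuals <- rep(c(1, -1), 4)
  expect_equal(residual_diagnostics(f)$fan_index, 0)

  # |residual| strictly increasing with fitted: perfect fan
  f$residuals <- (1:8) * c(1, -1)
  expect_equal(residual_diagnostics(f)$fan_index, 1)

  # matches an independent rank-correlation computation
  set.seed(5)
  f$fitted <- runif(8)
  f$residuals <- rnorm(8)
  d <- residual_diagnostics(f)
  oracle <- cor(rank(abs(f$residuals)), rank(f$fitted))
  expect_equal(d$fan_index, oracle, tolerance = 1e-12)
})

test_that("diagnostics degrade gracefully at tiny n and sort the smooth curve", {
  f <- fake_fit("sqrt_lm", "oneway", c("(Intercept)" = 1, g2 = 0),
                levels = c("g1", "g2"), n = 3)
  f$fitted <- c(3, 1, 2)
  f$residuals <- c(0.1, -0.2, 0.3)
  d <- residual_diagnostics(f)
  expect_equal(nrow(d$smooth_curve), 0) # smoothing skipped below n = 4
  expect_false(is.na(d$fan_index))

  d8 <- simulate_counts(count_config("oneway", n = 10, group_means = c(3, 12),
                                     seed = 2))
  diag <- residual_diagnostics(fit_ols(d8, transform_spec("sqrt")))
  expect_false(is.unsorted(diag$smooth_curve$fitted))
  expect_equal(diag$residual_type, "raw")
  dg <- residual_diagnostics(fit_glm_irls(d8, "poisson"))
  expect_equal(dg$residual_type, "deviance")
})

test_that("strongly heteroscedastic raw-scale data yields finite fan indices on both routes", {
  d <- simulate_counts(count_config("oneway", n = 40,
                                    group_means = c(2, 10, 60), seed = 21))
  for (f in list(fit_ols(d, transform_spec("sqrt")),
                 fit_glm_irls(d, "poisson"))) {
    fi <- residual_diagnostics(f)$fan_index
    expect_true(is.finite(fi) && fi >= -1 && fi <= 1)
  }
})

test_that("compare_routes assembles decisions, estimates and diagnostics for all routes", {
  d <- simulate_counts(count_config("oneway", n = 50, group_means = c(2, 20),
                                    seed = 33))
  cmp <- compare_routes(d)
  expect_setequal(cmp$decisions$route, c("sqrt_lm", "log_lm", "glm"))
  # strong effect: every route rejects, so decisions agree
  expect_true(all(cmp$decisions$decision))
  expect_true(cmp$decisions_agree)
  expect_equal(nrow(cmp$estimates), 6) # 3 routes x 2 group means
  expect_equal(nrow(cmp$pct_diff), 4) # 2 LM routes x 2 group means
  expect_true(all(cmp$pct_diff$pct_diff <= 0)) # Jensen: LM means below GLM
  # deterministic given the dataset
  cmp2 <- compare_routes(d)
  expect_identical(tidy(cmp), tidy(cmp2))
})

test_that("identical group samples give p-values of 1 and agreeing non-significant decisions", {
  # both groups hold the same multiset of counts: no between-group signal
  vals <- c(2, 5, 7, 3, 4, 6, 5, 4)
  d <- make_oneway(vals, vals)
  cmp <- compare_routes(d)
  expect_true(all(cmp$decisions$p_value > 0.999))
  expect_true(all(!cmp$decisions$decision))
  expect_true(cmp$decisions_agree)
})

test_that("constant dataset: GLM means equal the constant and sqrt pct_diff is zero", {
  d <- make_oneway(rep(4, 6), rep(4, 6))
  cmp <- suppressWarnings(compare_routes(d))
  glm_est <- cmp$estimates$estimate[cmp$estimates$route == "glm"]
  expect_equal(glm_est, c(4, 4), tolerance = 1e-9)
  sqrt_pd <- cmp$pct_diff$pct_diff[cmp$pct_diff$route == "sqrt_lm"]
  expect_equal(sqrt_pd, c(0, 0), tolerance = 1e-7)
})

test_that("a failing route aborts the comparison naming the route", {
  d <- make_regression(c(3, 1, 4, 2), rep(1, 4)) # constant covariate
  expect_error(compare_routes(d), "Route sqrt_lm failed")
})

test_that("run_case_suite counts decision changes and fan flags", {
  # identical p-values across routes by construction: same dataset repeated
  vals <- c(2, 5, 7, 3)
  d_null <- make_oneway(vals, vals)
  suite <- run_case_suite(list(a = d_null, b = d_null))
  expect_equal(suite$summary$n_decision_changes, 0)
  expect_equal(suite$summary$n_datasets, 2)

  # mix in a strong effect and a borderline case; recount independently
  datasets <- list(
    null1 = d_null,
    strong = simulate_counts(count_config("oneway", n = 50,
                                          group_means = c(2, 20), seed = 1)),
    medium = simulate_counts(count_config("oneway", n = 10,
                                          group_means = c(4, 8), seed = 2)),
    small = simulate_counts(count_config("oneway", n = 5,
                                         group_means = c(3, 6), seed = 3))
  )
  suite <- run_case_suite(datasets)
  expected_changes <- sum(vapply(suite$reports, function(r) {
    dec <- setNames(r$decisions$decision, r$decisions$route)
    dec[["sqrt_lm"]] != dec[["glm"]] || dec[["log_lm"]] != dec[["glm"]]
  }, logical(1)))
  expect_equal(suite$summary$n_decision_changes, expected_changes)
  expect_true(suite$summary$n_sqrt_more_fan >= 0 &&
                suite$summary$n_sqrt_more_fan <= 4)
  expect_named(suite$reports, names(datasets))
})

test_that("single null-simulated dataset yields counts within bounds", {
  d <- simulate_null(count_config("oneway", n = 30, group_means = c(5, 5),
                                  seed = 17))
  suite <- run_case_suite(list(d))
  expect_true(suite$summary$n_decision_changes %in% c(0, 1))
})
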