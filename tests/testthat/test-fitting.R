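test_that("OLS on transformed counts matches closed-form two-group solutions", {
  d <- make_oneway(c(1, 3), c(5, 5))
  f <- fit_ols(d, transform_spec("sqrt"))
  m <- c(f$coefficients[1], sum(f$coefficients))
  expect_equal(unname(m), c((1 + sqrt(3)) / 2, sqrt(5)), tolerance = 1e-12)
  # identical values in group 2 contribute nothing to the RSS
  expect_equal(f$scale_info$rss, sum((sqrt(c(1, 3)) - (1 + sqrt(3)) / 2)^2),
               tolerance = 1e-12)
})

test_that("two exact points give an exact line with zero RSS", {
  # sqrt(y) = 1, 3 at x = 0, 1
  f <- fit_ols(make_regression(c(1, 9), c(0, 1)), transform_spec("sqrt"))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_lt(f$scale_info$rss, 1e-20)
})

test_that("OLS coefficients equal the normal-equations solution", {
  set.seed(7)
  for (rep in 1:5) {
    d <- make_regression(rpois(12, 6), runif(12, 0, 3))
    spec <- transform_spec("log")
    f <- fit_ols(d, spec)
    X <- cbind(1, d$x)
    z <- log(d$y + 1)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% z)
    expect_lt(max(abs(f$coefficients - drop(beta_oracle))), 1e-8)
  }
})

test_that("intercept-only Poisson fit returns the log of the sample mean", {
  f <- fit_glm_irls(tibble::tibble(y = c(2L, 4L, 6L)), family = "poisson")
  expect_equal(unname(f$coefficients), log(4), tolerance = 1e-10)
  expect_true(is.na(f$p_value))
})

test_that("one-way log-link GLM reproduces group sample means", {
  d <- make_oneway(c(2, 3, 4), c(6, 7, 8)) # means 3 and 7
  f <- fit_glm_irls(d, family = "poisson")
  expect_equal(unname(f$coefficients), c(log(3), log(7 / 3)), tolerance = 1e-8)
  # holds for any one-way dataset (the group factor saturates the model)
  set.seed(12)
  for (rep in 1:5) {
    d <- make_oneway(rpois(9, 4) + 1, rpois(7, 11), rpois(8, 2) + 1)
    f <- fit_glm_irls(d, family = "poisson")
    gm <- tapply(d$y, d$x, mean)
    fitted_gm <- tapply(f$fitted, d$x, mean)
    expect_lt(max(abs(fitted_gm - gm)), 1e-8)
  }
})

test_that("IRLS agrees with direct likelihood maximization on small instances", {
  set.seed(31)
  for (rep in 1:10) {
    d <- if (rep %% 2 == 0) {
      make_oneway(rpois(sample(5:15, 1), 5) + 1, rpois(sample(5:15, 1), 12))
    } else {
      n <- sample(10:30, 1)
      x <- seq(0, 2, length.out = n)
      make_regression(rpois(n, exp(1 + 0.4 * x)), x)
    }
    f <- fit_glm_irls(d, family = "poisson")
    oracle <- oracle_glm_optim(oracle_design(d), d$y, "poisson")
    expect_lt(max(abs(f$coefficients - oracle)), 1e-6)
  }
})

test_that("NB IRLS with fixed theta matches the likelihood oracle and the Poisson limit", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 25
    d <- make_regression(rnbinom(n, mu = exp(1 + 0.3 * seq(0, 2, length.out = n)),
                                 size = 2),
                         seq(0, 2, length.out = n))
    f <- fit_glm_irls(d, family = "negbin", theta = 2)
    oracle <- oracle_glm_optim(oracle_design(d), d$y, "negbin", theta = 2)
    expect_lt(max(abs(f$coefficients - oracle)), 1e-6)

    f_pois <- fit_glm_irls(d, family = "poisson")
    f_limit <- fit_glm_irls(d, family = "negbin", theta = 1e8)
    expect_lt(max(abs(f_pois$coefficients - f_limit$coefficients)), 1e-6)
  }
})

test_that("estimated NB theta and coefficients agree with an established fitter", {
  set.seed(77)
  d <- simulate_counts(count_config("oneway", n = 60, group_means = c(4, 10),
                                    family = "negbin", theta = 1.5, seed = 8))
  f <- fit_glm_irls(d, family = "negbin")
  m <- MASS::glm.nb(y ~ x, data = d)
  expect_lt(max(abs(f$coefficients - coef(m))), 1e-4)
  expect_lt(abs(f$scale_info$theta - m$theta) / m$theta, 1e-3)
})

test_that("likelihood-ratio p-value matches the analysis-of-deviance oracle", {
  set.seed(19)
  for (rep in 1:5) {
    d <- make_oneway(rpois(12, 5), rpois(12, 8))
    f <- fit_glm_irls(d, family = "poisson")
    g <- glm(y ~ x, data = d, family = poisson())
    p_oracle <- anova(g, test = "Chisq")$`Pr(>Chi)`[2]
    expect_equal(f$p_value, p_oracle, tolerance = 1e-8)
  }
})

test_that("p-values are invariant to relabeling of group levels", {
  set.seed(23)
  d <- make_oneway(rpois(10, 3) + 1, rpois(10, 9), labels = c("a", "b"))
  d2 <- d
  d2$x <- factor(ifelse(d$x == "a", "z", "m")) # reverses reference group
  for (fit_fun in list(
    function(dd) fit_ols(dd, transform_spec("sqrt")),
    function(dd) fit_ols(dd, transform_spec("log")),
    function(dd) fit_glm_irls(dd, family = "poisson")
  )) {
    expect_equal(fit_fun(d)$p_value, fit_fun(d2)$p_value, tolerance = 1e-10)
  }
})

test_that("dispersion statistic is 0 for a perfect fit and near 1 under equidispersion", {
  # each group constant: fitted means equal the data exactly
  d <- make_oneway(c(4, 4, 4), c(9, 9, 9))
  f <- fit_glm_irls(d, family = "poisson")
  expect_equal(dispersion_statistic(f), 0, tolerance = 1e-12)

  d_eq <- simulate_counts(count_config("oneway", n = 5000,
                                       group_means = c(5, 5), seed = 9))
  f_eq <- fit_glm_irls(d_eq, family = "poisson")
  expect_gt(dispersion_statistic(f_eq), 0.9)
  expect_lt(dispersion_statistic(f_eq), 1.1)

  d_od <- simulate_counts(count_config("oneway", n = 5000,
                                       group_means = c(5, 5),
                                       family = "negbin", theta = 1, seed = 10))
  f_od <- fit_glm_irls(d_od, family = "poisson")
  expect_gt(dispersion_statistic(f_od), 2) # expectation approx 1 + mu/theta = 6
})

test_that("family choice follows the dispersion threshold", {
  d_eq <- simulate_counts(count_config("oneway", n = 2000,
                                       group_means = c(5, 5), seed = 14))
  expect_equal(as.character(choose_family(d_eq)), "poisson")

  d_od <- simulate_counts(count_config("oneway", n = 2000,
                                       group_means = c(5, 5),
                                       family = "negbin", theta = 0.5,
                                       seed = 15))
  expect_equal(as.character(choose_family(d_od)), "negbin")
  expect_equal(as.character(choose_family(d_od, threshold = Inf)), "poisson")
  expect_gt(attr(choose_family(d_od), "dispersion"), 1.5)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_glm_irls(make_oneway(c(0, 0), c(0, 0)), "poisson"),
               "All-zero")
  expect_error(fit_ols(make_regression(c(1, 2, 3), c(2, 2, 2)),
                       transform_spec("sqrt")), "rank deficient")
  expect_error(fit_ols(tibble::tibble(y = 1:3, x = c("a", "a", "a")),
                       transform_spec("sqrt")), "two groups")
})
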