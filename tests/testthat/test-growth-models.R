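test_that("linear fit is exact on noise-free lines and matches the OLS oracle", {
  s <- make_cumulative_series(2 + 3 * (1:10))
  f <- fit_linear(s)
  expect_equal(unname(f$params), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_lt(f$rss, 1e-18)

  flat <- fit_linear(make_cumulative_series(rep(7, 8)))
  expect_equal(unname(flat$params[["b"]]), 0)
  expect_equal(unname(flat$params[["a"]]), 7)

  withr::with_seed(21, {
    for (rep in 1:10) {
      t <- 1:15
      y <- 10 + 4 * t + rnorm(15, 0, 3)
      f <- fit_linear(make_cumulative_series(y))
      o <- ols_oracle(t, y)
      expect_equal(unname(f$params[["a"]]), o$a, tolerance = 1e-10)
      expect_equal(unname(f$params[["b"]]), o$b, tolerance = 1e-10)
      expect_equal(unname(f$std_errors[["a"]]), o$se_a, tolerance = 1e-10)
      expect_equal(unname(f$std_errors[["b"]]), o$se_b, tolerance = 1e-10)
    }
  })

  expect_error(fit_linear(make_cumulative_series(1:3)), "at least 4")
})

test_that("exponential fit recovers generating parameters and matches the grid oracle", {
  s <- simulate_series("exponential", list(alpha = 1198.5, beta = 0.0972),
                       n_years = 30)
  f <- fit_exponential(s)
  expect_equal(unname(f$params[["beta"]]), 0.0972, tolerance = 1e-8)
  expect_equal(unname(f$params[["alpha"]]), 1198.5, tolerance = 1e-6)

  # seeded noisy series against the beta-profiled grid-search oracle
  withr::with_seed(33, {
    for (rep in 1:5) {
      t <- 1:20
      y <- 80 * exp(0.15 * t) * exp(rnorm(20, 0, 0.05))
      f <- fit_exponential(make_cumulative_series(y))
      b_star <- exp_grid_oracle(t, y, c(0, 0.5))
      expect_equal(unname(f$params[["beta"]]), b_star, tolerance = 1e-3)
    }
  })

  # nls refinement reproduces a noise-free curve too
  fn <- fit_exponential(s, method = "nls")
  expect_equal(unname(fn$params[["beta"]]), 0.0972, tolerance = 1e-6)

  # leading zeros are dropped with a warning; interior fitting then proceeds
  lead <- make_series(c(0, 0, 3, 5, 9, 16, 28, 50))
  expect_warning(fl <- fit_exponential(lead), "leading zero")
  expect_equal(fl$n_obs, 6)
})

test_that("constant positive series has growth rate zero", {
  f <- suppressWarnings(fit_exponential(make_cumulative_series(rep(5, 10))))
  expect_equal(unname(f$params[["beta"]]), 0, tolerance = 1e-12)
  expect_equal(unname(f$params[["alpha"]]), 5, tolerance = 1e-10)
})

test_that("saturation fit recovers noise-free parameters and matches the grid oracle", {
  gen <- list(Y0 = 1106.6828, theta1 = 3694.5278, theta2 = 0.541521)
  s <- simulate_series("saturation_mm", gen, n_years = 18)
  f <- fit_saturation_mm(s)
  expect_equal(unname(f$params[["theta2"]]), gen$theta2, tolerance = 1e-6)
  expect_equal(unname(f$params[["Y0"]]), gen$Y0, tolerance = 1e-6)
  expect_equal(unname(f$params[["theta1"]]), gen$theta1, tolerance = 1e-6)

  # flat series: theta1 = 0 reproduces the curve exactly
  flat <- fit_saturation_mm(make_cumulative_series(rep(42, 8)))
  expect_equal(unname(flat$params[["theta1"]]), 0)
  expect_equal(flat$rss, 0)
  expect_true(flat$valid)

  withr::with_seed(55, {
    for (rep in 1:5) {
      t <- 1:12
      y <- 500 + 3000 * t / (2.5 + t) + rnorm(12, 0, 25)
      f <- fit_saturation_mm(make_cumulative_series(y))
      o <- mm_grid_oracle(t, y)
      expect_equal(unname(f$params[["theta2"]]), o$theta2, tolerance = 1e-2)
      expect_equal(unname(f$params[["Y0"]]), o$Y0, tolerance = 1e-2)
      expect_equal(unname(f$params[["theta1"]]), o$theta1, tolerance = 1e-2)
    }
  })
})

test_that("logistic fit recovers noise-free parameters, halves at the midpoint, matches the oracle", {
  gen <- list(L = 1e5, k = 0.5513, t0 = 5.7469)
  s <- simulate_series("logistic", gen, n_years = 25)
  f <- fit_logistic(s)
  expect_equal(unname(f$params[["k"]]), gen$k, tolerance = 1e-6)
  expect_equal(unname(f$params[["t0"]]), gen$t0, tolerance = 1e-6)
  expect_equal(unname(f$params[["L"]]), gen$L, tolerance = 1e-6)

  # at t = t0 the fitted curve equals L / 2 (logistic symmetry)
  at_mid <- growth_curve("logistic", f$params, f$params[["t0"]])
  expect_equal(at_mid, unname(f$params[["L"]]) / 2)

  withr::with_seed(77, {
    for (rep in 1:5) {
      t <- 1:12
      y <- 5000 / (1 + exp(-0.8 * (t - 6))) + rnorm(12, 0, 40)
      f <- fit_logistic(make_cumulative_series(y))
      o <- logistic_grid_oracle(t, y)
      expect_equal(unname(f$params[["k"]]), o$k, tolerance = 1e-2)
      expect_equal(unname(f$params[["t0"]]), o$t0, tolerance = 1e-2)
    }
  })
})

test_that("fit metrics follow the stated conventions", {
  obs <- c(1, -1, 2, -2) + 10
  m <- compute_fit_metrics(obs, rep(10, 4), n_params = 2)
  expect_equal(m$rss, 10)
  expect_equal(m$rmse, sqrt(2.5))

  perfect <- compute_fit_metrics(1:5, 1:5, n_params = 2)
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rss, 0)
  expect_identical(perfect$aic, -Inf)
  expect_identical(perfect$bic, -Inf)

  # bic - aic == p * (log(n) - 2) identically, and r2 <= 1, rss >= 0
  withr::with_seed(8, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      p <- sample(2:3, 1)
      obs <- rnorm(n, 50, 10)
      fit <- obs + rnorm(n)
      m <- compute_fit_metrics(obs, fit, p)
      expect_equal(m$bic - m$aic, p * (log(n) - 2), tolerance = 1e-12)
      expect_lte(m$r2, 1)
      expect_gte(m$rss, 0)
    }
  })
})

test_that("every fitter is scale equivariant", {
  specs <- list(
    list(family = "linear", params = list(a = 30, b = 12), scale = c("a", "b")),
    list(family = "exponential", params = list(alpha = 40, beta = 0.18),
         scale = "alpha"),
    list(family = "saturation_mm",
         params = list(Y0 = 800, theta1 = 4000, theta2 = 1.8), scale = c("Y0", "theta1")),
    list(family = "logistic", params = list(L = 30000, k = 0.6, t0 = 10),
         scale = "L")
  )
  for (sp in specs) {
    s <- simulate_series(sp$family, sp$params, n_years = 20,
                         noise = "gaussian_cumulative",
                         sd = 0.002 * max(growth_curve(sp$family, sp$params, 20)),
                         seed = 99)
    f1 <- fit_growth(s, sp$family)
    for (c_mult in c(0.5, 3)) {
      scaled <- dplyr::mutate(
        s,
        annual_count = annual_count * c_mult,
        cumulative_count = cumulative_count * c_mult
      )
      f2 <- fit_growth(scaled, sp$family)
      shape_terms <- setdiff(names(f1$params), sp$scale)
      tol <- if (sp$family %in% c("linear", "exponential")) 1e-10 else 1e-8
      expect_equal(f2$params[shape_terms], f1$params[shape_terms],
                   tolerance = tol)
      expect_equal(unname(f2$params[sp$scale]),
                   unname(c_mult * f1$params[sp$scale]), tolerance = tol)
    }
  }
})

test_that("NLS fits match exhaustive grid search on short series", {
  withr::with_seed(101, {
    t <- 1:12
    y_mm <- 200 + 1500 * t / (4 + t) + rnorm(12, 0, 15)
    y_lg <- 900 / (1 + exp(-0.7 * (t - 7))) + rnorm(12, 0, 10)
  })
  f_mm <- fit_saturation_mm(make_cumulative_series(y_mm))
  o_mm <- mm_grid_oracle(t, y_mm)
  expect_equal(unname(f_mm$params[["theta2"]]), o_mm$theta2, tolerance = 1e-2)
  f_lg <- fit_logistic(make_cumulative_series(y_lg))
  o_lg <- logistic_grid_oracle(t, y_lg)
  expect_equal(unname(f_lg$params[["k"]]), o_lg$k, tolerance = 1e-2)
  expect_equal(unname(f_lg$params[["t0"]]), o_lg$t0, tolerance = 1e-2)
})

test_that("residual diagnostics summarise location, autocorrelation and shape", {
  fake_fit <- function(res) {
    structure(
      list(residuals = res, fitted_values = seq_along(res) * 10 - res,
           drug_id = "X", family = "linear"),
      class = "growth_fit"
    )
  }
  zero <- residual_diagnostics(fake_fit(rep(0, 6)))
  expect_true(zero$degenerate)
  expect_equal(zero$mean, 0)
  expect_equal(zero$lag1_acf, 0)
  expect_true(is.na(zero$shapiro_p))

  alt <- c(1, -1, 1, -1, 1, -1)
  d <- residual_diagnostics(fake_fit(alt))
  ec <- alt - mean(alt)
  lag1_oracle <- sum(ec[-6] * ec[-1]) / sum(ec^2)
  expect_equal(d$lag1_acf, lag1_oracle)
  expect_lt(d$lag1_acf, 0)
  expect_equal(d$skewness, 0)

  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(residual_diagnostics(fake_fit(sym))$skewness, 0)
})

test_that("diagnostic plots are written on request", {
  s <- simulate_series("linear", list(a = 5, b = 20), n_years = 15,
                       noise = "gaussian_cumulative", sd = 10, seed = 2)
  f <- fit_linear(s)
  rf <- withr::local_tempfile(fileext = ".png")
  qq <- withr::local_tempfile(fileext = ".png")
  residual_diagnostics(f, plot_files = list(residual_fitted = rf, qq = qq))
  expect_true(file.exists(rf))
  expect_true(file.exists(qq))
})

test_that("fits serialise to JSON with parameters, intervals and flags", {
  f <- fit_linear(make_cumulative_series(2 + 3 * (1:10) + c(0.1, -0.1, rep(0, 8))))
  parsed <- jsonlite::fromJSON(growth_fit_json(f))
  expect_equal(parsed$family, "linear")
  expect_equal(parsed$params$b, unname(f$params[["b"]]))
  expect_equal(parsed$n_params, 2)
  expect_true(parsed$valid)
})
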