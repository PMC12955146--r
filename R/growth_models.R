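#' Fit-statistic conventions
#'
#' Least-squares information criteria used for all growth-model fits:
#' `AIC = n * log(RSS / n) + 2 * p` and `BIC = n * log(RSS / n) + p * log(n)`,
#' where `p` counts the mean-function parameters. With this convention
#' `BIC - AIC == p * (log(n) - 2)` identically, which the model-selection
#' tests rely on. A perfect fit (`RSS == 0`) makes the log diverge; both
#' criteria are then reported as `-Inf` together with a perfect-fit flag
#' rather than raising an error.
#'
#' @param rss Residual sum of squares (non-negative scalar).
#' @param n Number of observations.
#' @param n_params Number of fitted mean parameters `p`.
#' @return Named list with `aic` and `bic`.
#' @export
information_criteria <- function(rss, n, n_params) {
  stopifnot(rss >= 0, n >= 1, n_params >= 1)
  if (rss == 0) {
    return(list(aic = -Inf, bic = -Inf))
  }
  base <- n * log(rss / n)
  list(aic = base + 2 * n_params, bic = base + n_params * log(n))
}

#' Goodness-of-fit metrics on the cumulative scale
#'
#' Residual sum of squares, root-mean-square error (`sqrt(RSS/n)`), coefficient
#' of determination about the mean, and the RSS-based AIC/BIC (see
#' [information_criteria()]). All metrics are computed on the original
#' cumulative-count scale regardless of how the model was estimated.
#'
#' @param observed,fitted Numeric vectors of equal length `n >= 2`.
#' @param n_params Number of fitted mean parameters (must be `< n`).
#' @return List with `rss`, `rmse`, `r2`, `aic`, `bic`, `n_obs`, `n_params`
#'   and logical `perfect_fit`.
#' @export
compute_fit_metrics <- function(observed, fitted, n_params) {
  n <- length(observed)
  if (length(fitted) != n) {
    abort("`observed` and `fitted` must have equal length")
  }
  if (n < 2) abort("need at least 2 observations")
  if (n <= n_params) abort("need more observations than parameters")
  res <- observed - fitted
  rss <- sum(res^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss == 0) {
    if (rss == 0) 1 else NA_real_
  } else {
    1 - rss / tss
  }
  ic <- information_criteria(rss, n, n_params)
  list(
    rss = rss, rmse = sqrt(rss / n), r2 = r2,
    aic = ic$aic, bic = ic$bic,
    n_obs = n, n_params = as.integer(n_params),
    perfect_fit = rss == 0
  )
}

new_growth_fit <- function(family, drug, t, observed, fitted, params,
                           std_errors, method, flags = character()) {
  p <- N_PARAMS[[family]]
  m <- compute_fit_metrics(observed, fitted, p)
  dfree <- m$n_obs - p
  crit <- qt(0.975, dfree)
  ci <- tibble::tibble(
    term = names(params),
    lower = unname(params - crit * std_errors[names(params)]),
    upper = unname(params + crit * std_errors[names(params)])
  )
  if (m$perfect_fit) flags <- union(flags, "perfect_fit")
  structure(
    list(
      family = family, drug_id = drug, method = method,
      params = params, std_errors = std_errors[names(params)], ci95 = ci,
      t = t, observed = observed, fitted_values = fitted,
      residuals = observed - fitted,
      rss = m$rss, rmse = m$rmse, r2 = m$r2, aic = m$aic, bic = m$bic,
      n_obs = m$n_obs, n_params = m$n_params,
      valid = !"invalid" %in% flags, flags = flags
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> family:", x$family, " drug:", x$drug_id,
      " method:", x$method, "\n")
  est <- format(signif(x$params, 6))
  se <- format(signif(x$std_errors, 4))
  for (i in seq_along(est)) {
    cat("  ", names(x$params)[i], "=", est[i], " (se", se[i], ")\n")
  }
  cat(sprintf(
    "  n = %d  R2 = %.4f  RMSE = %.4f  AIC = %.4f  BIC = %.4f\n",
    x$n_obs, x$r2, x$rmse, x$aic, x$bic
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a straight line to a cumulative ADR curve
#'
#' Ordinary least squares of the cumulative count on the 1-based time index,
#' `Y = a + b*t`. A linear cumulative curve corresponds to a roughly constant
#' annual report count — the pattern expected for a drug whose use (and
#' per-use risk) has stabilised.
#'
#' @param data Single-drug series tibble from [read_annual_counts()] or
#'   [simulate_series()] (needs `cumulative_count`, optionally `time_index`).
#' @return A `growth_fit` object; see [tidy.growth_fit()] and
#'   [glance.growth_fit()] for tibble views. Wald 95% confidence intervals use
#'   the t distribution with `n - 2` degrees of freedom.
#' @examples
#' s <- simulate_series("linear", list(a = 2, b = 3), n_years = 10)
#' fit_linear(s)
#' @export
fit_linear <- function(data) {
  v <- series_vectors(data)
  if (length(v$y) < 4) abort("linear fit needs at least 4 observations")
  if (length(unique(v$t)) < 2) abort("degenerate time index: all values equal")
  fit <- lm(y ~ t, data = data.frame(t = v$t, y = v$y))
  est <- setNames(coef(fit), c("a", "b"))
  # suppressWarnings: summary.lm warns on noise-free (numerically perfect) fits
  se <- setNames(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    c("a", "b")
  )
  new_growth_fit(
    "linear", v$drug, v$t, v$y, unname(stats::fitted(fit)),
    est, se, method = "ols"
  )
}

#' Fit the exponential growth model (the Detriment-Index model)
#'
#' Fits `Y(t) = alpha * exp(beta * t)` to a cumulative ADR curve. `beta`, the
#' relative growth rate per year, is the Detriment Index: it is unchanged when
#' every count is multiplied by a positive constant (only `alpha` absorbs the
#' scale), which is what makes it comparable across drugs with very different
#' reporting volumes.
#'
#' The default `log_linear` method regresses `log(Y)` on `t` by OLS — a
#' deterministic closed form whose `beta` is exactly scale invariant; fit
#' statistics are then computed on the original cumulative scale from
#' `Y - alpha * exp(beta * t)`. Leading zero cumulative values (years before
#' the first report) are dropped with a warning since `log(0)` is undefined;
#' on a cumulative curve zeros can only occur as a leading run. The `nls`
#' method refines the log-linear solution by Levenberg-Marquardt least squares
#' on the original scale.
#'
#' @inheritParams fit_linear
#' @param method `"log_linear"` (default) or `"nls"`.
#' @return A `growth_fit` with parameters `alpha`, `beta`. For `log_linear`
#'   the `beta` interval is the OLS slope interval (t distribution, `n - 2`
#'   df) and the `alpha` interval the delta-method interval.
#' @examples
#' s <- simulate_series("exponential", list(alpha = 1198.5, beta = 0.0972),
#'                      n_years = 30)
#' fit_exponential(s)
#' @export
fit_exponential <- function(data, method = c("log_linear", "nls")) {
  method <- match.arg(method)
  v <- series_vectors(data)
  t <- v$t
  y <- v$y
  lead0 <- y <= 0 & cumsum(y) == 0
  if (any(y[!lead0] <= 0)) {
    abort(paste0(
      "non-positive cumulative counts after the first report; ",
      "exponential fitting is infeasible for this series"
    ))
  }
  if (any(lead0)) {
    warn(paste0(
      "dropping ", sum(lead0),
      " leading zero cumulative value(s) before exponential fitting"
    ))
    t <- t[!lead0]
    y <- y[!lead0]
  }
  if (length(y) < 4) abort("exponential fit needs at least 4 positive observations")

  ll <- lm(ly ~ t, data = data.frame(t = t, ly = log(y)))
  cf <- coef(ll)
  se_ll <- suppressWarnings(summary(ll)$coefficients[, "Std. Error"])
  alpha <- exp(cf[[1]])
  beta <- cf[[2]]

  if (method == "log_linear") {
    est <- c(alpha = alpha, beta = beta)
    # delta method for alpha = exp(intercept)
    se <- c(alpha = alpha * se_ll[[1]], beta = se_ll[[2]])
    fitted <- alpha * exp(beta * t)
    return(new_growth_fit("exponential", v$drug, t, y, fitted, est, se,
                          method = "log_linear"))
  }

  # Least squares is solved on the unit-scaled response y / max(y): the
  # optimum is identical up to the scale parameter, conditioning is better,
  # and beta inherits (near-)exact scale invariance.
  s <- max(y)
  fit <- try(
    minpack.lm::nlsLM(
      ys ~ alpha * exp(beta * t),
      data = data.frame(t = t, ys = y / s),
      start = list(alpha = alpha / s, beta = beta),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-12)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    abort(paste0(
      "exponential nls did not converge (last log-linear iterate: alpha = ",
      signif(alpha, 6), ", beta = ", signif(beta, 6), "): ",
      attr(fit, "condition")$message
    ))
  }
  est <- coef(fit)[c("alpha", "beta")] * c(s, 1)
  se <- summary(fit)$coefficients[c("alpha", "beta"), "Std. Error"] * c(s, 1)
  new_growth_fit("exponential", v$drug, t, y, s * unname(stats::fitted(fit)),
                 est, setNames(se, names(est)), method = "nls")
}

#' Fit the shifted Michaelis-Menten saturation model
#'
#' Nonlinear least squares for `Y = Y0 + theta1 * t / (theta2 + t)`: a curve
#' that starts at a non-zero baseline `Y0`, rises quickly and approaches the
#' asymptote `Y0 + theta1`, with `theta2` the time at which half the rise has
#' occurred. This is the expected shape for a drug whose reporting momentum is
#' exhausted after an effective market withdrawal. Starting values follow a
#' fixed rule (baseline from the first observation, rise from the range, half
#' rise time from the data); Levenberg-Marquardt iterations are capped at 500
#' with a 1e-10 tolerance. A fit with `theta2 <= 0` or `theta1 < 0` is flagged
#' invalid and excluded from model selection rather than raising an error.
#'
#' @inheritParams fit_linear
#' @return A `growth_fit` with parameters `Y0`, `theta1`, `theta2`; asymptotic
#'   standard errors from the Jacobian, 95% intervals from the t distribution
#'   with `n - 3` df.
#' @export
fit_saturation_mm <- function(data) {
  v <- series_vectors(data)
  t <- v$t
  y <- v$y
  if (length(y) < 5) abort("saturation fit needs at least 5 observations")

  if (diff(range(y)) == 0) {
    # Flat series: theta1 = 0 reproduces it exactly; theta2 is then
    # unidentifiable (Levenberg-Marquardt sees a singular gradient), so fix it.
    est <- c(Y0 = y[1], theta1 = 0, theta2 = 1)
    se <- c(Y0 = 0, theta1 = 0, theta2 = NA_real_)
    return(new_growth_fit("saturation_mm", v$drug, t, y, rep(y[1], length(y)),
                          est, se, method = "nls",
                          flags = "theta2_unidentifiable"))
  }

  y0_init <- y[1]
  th1_init <- max(y[length(y)] - y[1], 1e-8)
  half <- y0_init + th1_init / 2
  th2_init <- t[which(y >= half)[1]]
  if (is.na(th2_init) || th2_init <= 0) th2_init <- stats::median(t)

  # fit on the unit-scaled response (see fit_exponential)
  s <- max(abs(y))
  fit <- try(
    minpack.lm::nlsLM(
      ys ~ Y0 + theta1 * t / (theta2 + t),
      data = data.frame(t = t, ys = y / s),
      start = list(Y0 = y0_init / s, theta1 = th1_init / s, theta2 = th2_init),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-12)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    abort(paste0("saturation fit did not converge: ",
                 attr(fit, "condition")$message))
  }
  est <- coef(fit)[c("Y0", "theta1", "theta2")] * c(s, s, 1)
  se <- summary(fit)$coefficients[names(est), "Std. Error"] * c(s, s, 1)
  flags <- character()
  if (est[["theta2"]] <= 0 || est[["theta1"]] < 0) flags <- "invalid"
  new_growth_fit("saturation_mm", v$drug, t, y,
                 s * unname(stats::fitted(fit)),
                 est, setNames(se, names(est)), method = "nls", flags = flags)
}

#' Fit the logistic (sigmoidal) growth model
#'
#' Nonlinear least squares for `Y = L / (1 + exp(-k * (t - t0)))`: an S-shaped
#' cumulative curve with upper asymptote `L`, growth rate `k` and midpoint
#' `t0` (the inflection year, at which the fitted value equals `L / 2`).
#' Post-withdrawal reporting that keeps rising for years before levelling off
#' follows this shape. Starting values are fixed: `L` at 1.05 times the
#' maximum, `t0` where the series first exceeds half of that, and `k` from the
#' slope of the logit-linearised regression. A fit with `k <= 0` or `L <= 0`
#' is flagged invalid and excluded from model selection.
#'
#' @inheritParams fit_linear
#' @return A `growth_fit` with parameters `L`, `k`, `t0` and t-based 95%
#'   intervals (`n - 3` df).
#' @export
fit_logistic <- function(data) {
  v <- series_vectors(data)
  t <- v$t
  y <- v$y
  if (length(y) < 5) abort("logistic fit needs at least 5 observations")

  if (diff(range(y)) == 0) {
    est <- c(L = max(2 * y[1], 1), k = 0, t0 = stats::median(t))
    se <- c(L = NA_real_, k = NA_real_, t0 = NA_real_)
    return(new_growth_fit("logistic", v$drug, t, y, rep(y[1], length(y)),
                          est, se, method = "nls", flags = "invalid"))
  }

  L_init <- 1.05 * max(y)
  t0_init <- t[which(y > L_init / 2)[1]]
  if (is.na(t0_init)) t0_init <- stats::median(t)
  z <- log(pmax(y, L_init * 1e-6) / pmax(L_init - y, L_init * 1e-6))
  k_init <- coef(lm(z ~ t))[[2]]
  if (!is.finite(k_init) || k_init <= 0) k_init <- 0.5

  # fit on the unit-scaled response (see fit_exponential)
  s <- max(abs(y))
  fit <- try(
    minpack.lm::nlsLM(
      ys ~ L / (1 + exp(-k * (t - t0))),
      data = data.frame(t = t, ys = y / s),
      start = list(L = L_init / s, k = k_init, t0 = t0_init),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-12)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    abort(paste0("logistic fit did not converge: ",
                 attr(fit, "condition")$message))
  }
  est <- coef(fit)[c("L", "k", "t0")] * c(s, 1, 1)
  se <- summary(fit)$coefficients[names(est), "Std. Error"] * c(s, 1, 1)
  flags <- character()
  if (est[["k"]] <= 0 || est[["L"]] <= 0) flags <- "invalid"
  new_growth_fit("logistic", v$drug, t, y, s * unname(stats::fitted(fit)),
                 est, setNames(se, names(est)), method = "nls", flags = flags)
}

#' Fit one named growth family
#'
#' Dispatcher over the four family fitters; useful with [purrr::map()] when
#' fitting several families to one series.
#'
#' @inheritParams fit_exponential
#' @param family One of `"linear"`, `"exponential"`, `"saturation_mm"`,
#'   `"logistic"`.
#' @return A `growth_fit`.
#' @export
fit_growth <- function(data, family = c("linear", "exponential",
                                        "saturation_mm", "logistic"),
                       method = c("log_linear", "nls")) {
  family <- match.arg(family)
  switch(family,
    linear = fit_linear(data),
    exponential = fit_exponential(data, method = match.arg(method)),
    saturation_mm = fit_saturation_mm(data),
    logistic = fit_logistic(data)
  )
}

#' Residual diagnostics for a growth fit
#'
#' Numeric residual summaries on the cumulative scale: mean, standard
#' deviation, skewness, lag-1 autocorrelation, Shapiro-Wilk normality p-value
#' and the extreme standardised residuals. Cumulative-curve residuals are
#' typically autocorrelated even for a well-chosen family; the lag-1
#' autocorrelation quantifies this but is reported, not modelled. Optional
#' residual-vs-fitted and normal Q-Q plots can be written to files.
#'
#' @param fit A `growth_fit`.
#' @param plot_files Optional named list/vector with elements
#'   `residual_fitted` and/or `qq`: file paths to write the plots to
#'   (any device [ggplot2::ggsave()] understands).
#' @return One-row tibble with columns `mean`, `sd`, `skewness`, `lag1_acf`,
#'   `shapiro_p`, `std_resid_min`, `std_resid_max`, `degenerate`. A
#'   zero-variance residual vector yields zeros with `degenerate = TRUE` and
#'   no normality test.
#' @export
residual_diagnostics <- function(fit, plot_files = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  e <- fit$residuals
  if (length(e) < 5) abort("diagnostics need at least 5 residuals")
  s <- sd(e)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    out <- tibble::tibble(
      mean = 0, sd = 0, skewness = 0, lag1_acf = 0,
      shapiro_p = NA_real_, std_resid_min = 0, std_resid_max = 0,
      degenerate = TRUE
    )
  } else {
    ec <- e - mean(e)
    lag1 <- sum(ec[-length(ec)] * ec[-1]) / sum(ec^2)
    std <- ec / s
    out <- tibble::tibble(
      mean = mean(e), sd = s,
      skewness = e1071::skewness(e, type = 1),
      lag1_acf = lag1,
      shapiro_p = shapiro.test(e)$p.value,
      std_resid_min = min(std), std_resid_max = max(std),
      degenerate = FALSE
    )
  }
  if (!is.null(plot_files)) {
    df <- tibble::tibble(fitted = fit$fitted_values, residual = e)
    if (!is.null(plot_files[["residual_fitted"]])) {
      p <- ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$residual)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::geom_point() +
        ggplot2::labs(
          x = "Fitted cumulative count", y = "Residual",
          title = paste0(fit$drug_id, ": residuals vs fitted (", fit$family, ")")
        )
      ggplot2::ggsave(plot_files[["residual_fitted"]], p,
                      width = 5, height = 4)
    }
    if (!is.null(plot_files[["qq"]])) {
      p <- ggplot2::ggplot(df, ggplot2::aes(sample = .data$residual)) +
        ggplot2::stat_qq() + ggplot2::stat_qq_line() +
        ggplot2::labs(title = paste0(fit$drug_id, ": residual normal Q-Q"))
      ggplot2::ggsave(plot_files[["qq"]], p, width = 5, height = 4)
    }
  }
  out
}

#' Serialise a growth fit as JSON
#'
#' @param fit A `growth_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
growth_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  obj <- list(
    family = fit$family, drug = fit$drug_id, method = fit$method,
    params = as.list(fit$params), std_errors = as.list(fit$std_errors),
    ci95 = fit$ci95,
    metrics = list(rss = fit$rss, rmse = fit$rmse, r2 = fit$r2,
                   aic = fit$aic, bic = fit$bic),
    n_obs = fit$n_obs, n_params = fit$n_params,
    valid = fit$valid, flags = as.list(fit$flags)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(json)
}
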