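# Shared fixtures and independent oracles used across the suite.

# Build a tidy series from raw annual counts via the ingestion path.
make_series <- function(counts, drug = "X", start = 2000) {
  read_annual_counts(tibble::tibble(
    drug = drug, year = start + seq_along(counts) - 1, count = counts
  ))
}

# Wrap an arbitrary cumulative curve (possibly non-integer) as a series
# tibble without going through count validation.
make_cumulative_series <- function(y, drug = "X") {
  tibble::tibble(
    drug = drug, year = 2000 + seq_along(y) - 1,
    time_index = seq_along(y),
    annual_count = diff(c(0, y)), cumulative_count = y
  )
}

# Textbook closed-form simple OLS.
ols_oracle <- function(t, y) {
  n <- length(t)
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  a <- mean(y) - b * mean(t)
  res <- y - a - b * t
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sum((t - mean(t))^2))
  se_a <- sqrt(s2 * (1 / n + mean(t)^2 / sum((t - mean(t))^2)))
  list(a = a, b = b, se_a = se_a, se_b = se_b)
}

# Log-scale grid search for the exponential growth rate: for fixed beta the
# optimal log(alpha) is the mean of log(y) - beta * t, so only beta is
# scanned. Independent of the lm() route used by the package.
exp_grid_oracle <- function(t, y, beta_range = c(-1, 1), n_grid = 40001) {
  betas <- seq(beta_range[1], beta_range[2], length.out = n_grid)
  obj <- vapply(betas, function(b) {
    la <- mean(log(y) - b * t)
    sum((log(y) - la - b * t)^2)
  }, numeric(1))
  betas[which.min(obj)]
}

# Shifted Michaelis-Menten oracle: theta2 is scanned on a coarse grid and
# refined with optimize(); for fixed theta2 the model is linear in
# (Y0, theta1), so both are profiled out exactly by OLS.
mm_grid_oracle <- function(t, y, th2_range = c(1e-3, 50)) {
  prof_rss <- function(th2) {
    x <- t / (th2 + t)
    f <- lm(y ~ x)
    sum(resid(f)^2)
  }
  grid <- seq(th2_range[1], th2_range[2], length.out = 2000)
  best <- grid[which.min(vapply(grid, prof_rss, numeric(1)))]
  lo <- max(th2_range[1], best - diff(th2_range) / 1999)
  hi <- min(th2_range[2], best + diff(th2_range) / 1999)
  th2 <- optimize(prof_rss, c(lo, hi), tol = 1e-12)$minimum
  cf <- coef(lm(y ~ I(t / (th2 + t))))
  list(Y0 = unname(cf[1]), theta1 = unname(cf[2]), theta2 = th2)
}

# Logistic oracle: coarse grid over (k, t0) with L profiled analytically
# (least squares of y on the unit logistic curve), then Nelder-Mead refine.
logistic_grid_oracle <- function(t, y) {
  prof <- function(p) {
    g <- 1 / (1 + exp(-p[1] * (t - p[2])))
    L <- sum(y * g) / sum(g^2)
    sum((y - L * g)^2)
  }
  grid <- expand.grid(
    k = seq(0.05, 2, length.out = 60),
    t0 = seq(min(t), max(t), length.out = 60)
  )
  rss <- apply(grid, 1, prof)
  start <- as.numeric(grid[which.min(rss), ])
  fit <- optim(start, prof, control = list(reltol = 1e-14, maxit = 5000))
  g <- 1 / (1 + exp(-fit$par[1] * (t - fit$par[2])))
  list(k = fit$par[1], t0 = fit$par[2], L = sum(y * g) / sum(g^2))
}

# Mid-range generating parameters shared by the simulation studies.
study_grid <- function(n_years = 25, noise = "poisson_increments") {
  tibble::tibble(
    family = c("saturation_mm", "linear", "exponential", "logistic"),
    params = list(
      list(Y0 = 1000, theta1 = 5000, theta2 = 2),
      list(a = 50, b = 100),
      list(alpha = 50, beta = 0.2),
      list(L = 20000, k = 0.5, t0 = 12)
    ),
    n_years = n_years,
    noise = noise
  )
}
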