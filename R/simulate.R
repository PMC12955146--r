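#' Deterministic growth curve for a family
#'
#' Evaluates the noise-free cumulative curve `F(t)` for one growth family at
#' the given time points. Parameterisations: linear `a + b*t`; exponential
#' `alpha * exp(beta * t)`; saturation `Y0 + theta1 * t / (theta2 + t)`;
#' logistic `L / (1 + exp(-k * (t - t0)))`.
#'
#' @param family One of `"linear"`, `"exponential"`, `"saturation_mm"`,
#'   `"logistic"`.
#' @param params Named list/vector of the family's parameters.
#' @param t Numeric vector of time points.
#' @return Numeric vector `F(t)`.
#' @export
growth_curve <- function(family = c("linear", "exponential",
                                    "saturation_mm", "logistic"),
                         params, t) {
  family <- match.arg(family)
  p <- as.list(params)
  need <- switch(family,
    linear = c("a", "b"),
    exponential = c("alpha", "beta"),
    saturation_mm = c("Y0", "theta1", "theta2"),
    logistic = c("L", "k", "t0")
  )
  missing_p <- setdiff(need, names(p))
  if (length(missing_p) > 0) {
    abort(paste0(family, " curve needs parameter(s): ",
                 paste(missing_p, collapse = ", ")))
  }
  switch(family,
    linear = p$a + p$b * t,
    exponential = {
      if (p$alpha <= 0) abort("exponential requires alpha > 0")
      p$alpha * exp(p$beta * t)
    },
    saturation_mm = {
      if (p$theta2 <= 0) abort("saturation requires theta2 > 0")
      if (p$theta1 < 0) abort("saturation requires theta1 >= 0")
      p$Y0 + p$theta1 * t / (p$theta2 + t)
    },
    logistic = {
      if (p$L <= 0 || p$k <= 0) abort("logistic requires L > 0 and k > 0")
      p$L / (1 + exp(-p$k * (t - p$t0)))
    }
  )
}

#' Simulate a synthetic ADR reporting series
#'
#' Generates one drug's annual/cumulative report series from a known growth
#' family, for use in recovery and classification studies. The deterministic
#' curve `F(t)` is evaluated at `t = 1..n_years` (with `F(0) := 0` for
#' increments) and noise is applied:
#'
#' * `none` — cumulative counts equal `F(t)` exactly;
#' * `poisson_increments` — annual increments are drawn
#'   `Poisson(F(t) - F(t-1))` and cumulated, giving integer, non-decreasing
#'   counts (requires a non-decreasing `F`); this is the natural count-noise
#'   model for report tallies;
#' * `gaussian_cumulative` — iid `N(0, sd)` noise is added to `F(t)`, then
#'   the curve is clipped to be non-negative and non-decreasing; this matches
#'   the homoscedastic least-squares assumption under which the models are
#'   fitted.
#'
#' An optional `spike` adds a stimulated-reporting bump — the transient
#' inflation of reports that follows publicity or regulatory action — to a
#' single annual increment. All randomness flows from `seed` via a local RNG
#' scope; the global random state is untouched and the same seed always
#' reproduces the same series.
#'
#' @inheritParams growth_curve
#' @param n_years Number of annual points (>= 6).
#' @param noise `"none"`, `"poisson_increments"` or `"gaussian_cumulative"`.
#' @param sd Noise standard deviation for `gaussian_cumulative`.
#' @param spike Optional list/vector with `year_index` (1..n_years) and
#'   `magnitude` (added to that year's annual increment).
#' @param seed Integer seed; required for the stochastic noise models.
#' @param drug_id Drug label for the output (default `"sim"`).
#' @param start_year First calendar year of the series (default 2000).
#' @return Series tibble with columns `drug`, `year`, `time_index`,
#'   `annual_count`, `cumulative_count`, directly usable by every fitter.
#' @examples
#' simulate_series("exponential", list(alpha = 2, beta = 0.3), n_years = 10)
#' simulate_series("linear", list(a = 5, b = 20), n_years = 15,
#'                 noise = "poisson_increments", seed = 42)
#' @export
simulate_series <- function(family, params, n_years,
                            noise = c("none", "poisson_increments",
                                      "gaussian_cumulative"),
                            sd = NULL, spike = NULL, seed = NULL,
                            drug_id = "sim", start_year = 2000L) {
  noise <- match.arg(noise)
  if (n_years < 6) abort("`n_years` must be at least 6")
  t <- seq_len(n_years)
  f <- growth_curve(family, params, t)
  increments <- diff(c(0, f))

  if (noise != "none" && is.null(seed)) {
    abort("stochastic noise requires an integer `seed`")
  }
  if (noise == "poisson_increments" && any(increments < -1e-9)) {
    abort(paste0(
      "poisson_increments requires a non-decreasing deterministic curve; ",
      "negative increment at t = ", which(increments < -1e-9)[1]
    ))
  }

  gen <- function() {
    cum <- switch(noise,
      none = f,
      poisson_increments = cumsum(rpois(n_years, pmax(increments, 0))),
      gaussian_cumulative = {
        if (is.null(sd) || sd < 0) abort("gaussian_cumulative requires `sd` >= 0")
        cummax(pmax(f + rnorm(n_years, 0, sd), 0))
      }
    )
    annual <- diff(c(0, cum))
    if (!is.null(spike)) {
      sp <- as.list(spike)
      idx <- as.integer(sp$year_index)
      if (is.na(idx) || idx < 1 || idx > n_years) {
        abort("`spike$year_index` must lie within 1..n_years")
      }
      annual[idx] <- annual[idx] + sp$magnitude
      cum <- cumsum(annual)
    }
    list(annual = annual, cum = cum)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  tibble::tibble(
    drug = drug_id,
    year = as.integer(start_year) + t - 1L,
    time_index = t,
    annual_count = out$annual,
    cumulative_count = out$cum
  )
}

# Deterministic per-replicate seeds derived from one master seed, kept below
# 2^31 so they are valid R integers.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parameter-recovery study for the Detriment Index
#'
#' For each cell of a simulation grid, repeatedly simulates a series and
#' re-estimates the exponential growth rate `beta` with [detriment_index()],
#' summarising bias, root-mean-square error and 95% CI coverage against the
#' generating value. Bias and coverage are defined only for cells generated
#' from the exponential family (whose `params` contain `beta`); other
#' families have no true `beta` and get `NA` summaries for those columns.
#' Fully reproducible from `(grid, replicates, seed)`; per-replicate fit
#' failures are counted, never fatal.
#'
#' @param grid Tibble with columns `family`, `params` (list-column of named
#'   parameter lists), `n_years`, `noise`, and optionally `sd` and `spike`
#'   (list-column).
#' @param replicates Replicates per cell (>= 1).
#' @param seed Master integer seed.
#' @param method Passed to [detriment_index()].
#' @return Tibble, one row per grid cell: the cell descriptors plus
#'   `true_beta`, `mean_beta`, `bias`, `rmse`, `coverage`, `n_fail`.
#' @export
run_recovery_study <- function(grid, replicates, seed,
                               method = c("log_linear", "nls")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(grid), replicates >= 1)
  seeds <- matrix(derive_seeds(seed, nrow(grid) * replicates),
                  nrow = nrow(grid))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    params <- cell$params[[1]]
    true_beta <- params[["beta"]] %||% NA_real_
    est <- purrr::map(seq_len(replicates), function(r) {
      s <- simulate_series(
        family = cell$family, params = params, n_years = cell$n_years,
        noise = cell$noise,
        sd = if ("sd" %in% names(cell)) cell$sd else NULL,
        spike = if ("spike" %in% names(cell)) cell$spike[[1]] else NULL,
        seed = seeds[i, r]
      )
      tryCatch(
        suppressWarnings(detriment_index(s, method = method)),
        error = function(e) NULL
      )
    })
    ok <- !purrr::map_lgl(est, is.null)
    betas <- purrr::map_dbl(est[ok], "beta")
    covered <- if (is.na(true_beta)) NA else mean(
      purrr::map_lgl(est[ok], \(d) d$beta_lo <= true_beta & true_beta <= d$beta_hi)
    )
    tibble::tibble(
      family = cell$family, n_years = cell$n_years, noise = cell$noise,
      true_beta = true_beta,
      mean_beta = mean(betas),
      bias = if (is.na(true_beta)) NA_real_ else mean(betas) - true_beta,
      rmse = if (is.na(true_beta)) NA_real_ else
        sqrt(mean((betas - true_beta)^2)),
      coverage = covered,
      n_fail = sum(!ok)
    )
  })
}

#' Classification-accuracy study
#'
#' For each grid cell, simulates `replicates` series from the generating
#' family and classifies each with [classify_pattern()], returning the
#' confusion counts: how often each generating family was assigned each
#' pattern label. Row sums always equal the replicate count. Fully
#' reproducible from `(grid, replicates, seed)`.
#'
#' @inheritParams run_recovery_study
#' @param ... Passed to [classify_pattern()].
#' @return Tibble, one row per grid cell: cell descriptors, one count column
#'   per label (`saturation`, `linear`, `exponential`, `sigmoidal`,
#'   `undetermined`) and `accuracy` (share assigned the generating family's
#'   own label).
#' @export
run_classification_study <- function(grid, replicates, seed, ...) {
  stopifnot(is.data.frame(grid), replicates >= 1)
  labels <- c(unname(FAMILIES), "undetermined")
  seeds <- matrix(derive_seeds(seed, nrow(grid) * replicates),
                  nrow = nrow(grid))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    assigned <- purrr::map_chr(seq_len(replicates), function(r) {
      s <- simulate_series(
        family = cell$family, params = cell$params[[1]],
        n_years = cell$n_years, noise = cell$noise,
        sd = if ("sd" %in% names(cell)) cell$sd else NULL,
        spike = if ("spike" %in% names(cell)) cell$spike[[1]] else NULL,
        seed = seeds[i, r]
      )
      tryCatch(
        suppressWarnings(classify_pattern(s, ...))$label,
        error = function(e) "undetermined"
      )
    })
    counts <- table(factor(assigned, levels = labels))
    out <- tibble::tibble(
      family = cell$family, n_years = cell$n_years, noise = cell$noise
    )
    out[labels] <- as.list(as.integer(counts))
    out$accuracy <- unname(counts[FAMILIES[[cell$family]]] / replicates)
    out
  })
}
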