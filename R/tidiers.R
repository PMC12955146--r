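#' Tidy a growth fit into a coefficient table
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (95% Wald intervals, t distribution).
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$std_errors),
    conf.low = x$ci95$lower,
    conf.high = x$ci95$upper
  )
}

#' One-row summary of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with `drug`, `family`, `method`, `r.squared`, `rss`,
#'   `rmse`, `AIC`, `BIC`, `nobs`, `df`, `valid`, `perfect.fit`.
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    drug = x$drug_id, family = x$family, method = x$method,
    r.squared = x$r2, rss = x$rss, rmse = x$rmse,
    AIC = x$aic, BIC = x$bic,
    nobs = x$n_obs, df = x$n_obs - x$n_params,
    valid = x$valid, perfect.fit = "perfect_fit" %in% x$flags
  )
}

#' Observation-level results for a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with `t`, `observed`, `.fitted`, `.resid`.
#' @exportS3Method generics::augment
augment.growth_fit <- function(x, ...) {
  tibble::tibble(
    t = x$t, observed = x$observed,
    .fitted = x$fitted_values, .resid = x$residuals
  )
}

#' Per-family model-selection scores of a classification
#'
#' @param x A `pattern_classification`.
#' @param ... Unused.
#' @return The per-family score tibble (`family`, `n_params`, `aic`, `bic`,
#'   `r2`, `rmse`, `valid`, `delta_aic`).
#' @exportS3Method generics::tidy
tidy.pattern_classification <- function(x, ...) {
  x$scores
}

#' One-row summary of a classification
#'
#' @param x A `pattern_classification`.
#' @param ... Unused.
#' @return Tibble with `drug`, `label`, the four per-family AICs,
#'   `delta_aic_winner` (AIC gap from the winner to the closest other valid
#'   family; `Inf` when only one family is valid) and `r2_winner`.
#' @exportS3Method generics::glance
glance.pattern_classification <- function(x, ...) {
  sc <- x$scores
  aic_of <- function(fam) sc$aic[match(fam, sc$family)]
  win <- if (is.null(x$best_fit)) NA_character_ else x$best_fit$family
  gap <- NA_real_
  r2w <- NA_real_
  if (!is.null(x$best_fit)) {
    others <- sc$valid & sc$family != win
    gap <- if (any(others)) min(sc$aic[others]) - x$best_fit$aic else Inf
    r2w <- x$best_fit$r2
  }
  tibble::tibble(
    drug = x$drug_id, label = x$label,
    aic_linear = aic_of("linear"),
    aic_exponential = aic_of("exponential"),
    aic_saturation = aic_of("saturation_mm"),
    aic_logistic = aic_of("logistic"),
    delta_aic_winner = gap,
    r2_winner = r2w
  )
}
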