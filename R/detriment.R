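#' Compute the Detriment Index for one drug
#'
#' The Detriment Index is the growth-rate parameter `beta` of the exponential
#' model `Y(t) = alpha * exp(beta * t)` fitted to a drug's cumulative ADR
#' curve (see [fit_exponential()]). A higher `beta` means a faster relative
#' accumulation of adverse-event reports and hence a less favourable safety
#' profile; `beta = 0` corresponds to a completely flat cumulative curve.
#' Because rescaling every count by a positive constant changes only `alpha`,
#' `beta` ranks drugs on a common scale irrespective of reporting volume or
#' market size.
#'
#' A flat series (all cumulative counts equal, including all-zero) returns
#' `beta = 0` by convention without fitting, avoiding `log(0)` failures.
#'
#' @inheritParams fit_exponential
#' @param composite Also compute the experimental `beta` x normalised-AUC
#'   composite (see [composite_index()]); off by default and never used for
#'   the default ranking.
#' @return One-row tibble: `drug`, `beta`, `beta_lo`, `beta_hi`, `alpha`,
#'   `r2`, `flat` (logical), plus `composite` when requested.
#' @examples
#' s <- simulate_series("exponential", list(alpha = 1198.5, beta = 0.0972),
#'                      n_years = 30)
#' detriment_index(s)
#' @export
detriment_index <- function(data, method = c("log_linear", "nls"),
                            composite = FALSE) {
  method <- match.arg(method)
  v <- series_vectors(data)
  if (diff(range(v$y)) == 0) {
    out <- tibble::tibble(
      drug = v$drug, beta = 0, beta_lo = 0, beta_hi = 0,
      alpha = v$y[1], r2 = 1, flat = TRUE
    )
  } else {
    fit <- fit_exponential(data, method = method)
    ci <- fit$ci95[fit$ci95$term == "beta", ]
    out <- tibble::tibble(
      drug = v$drug, beta = unname(fit$params[["beta"]]),
      beta_lo = ci$lower, beta_hi = ci$upper,
      alpha = unname(fit$params[["alpha"]]), r2 = fit$r2, flat = FALSE
    )
  }
  if (composite) out$composite <- composite_index(data, method = method)
  out
}

#' Check scale invariance of the Detriment Index
#'
#' Multiplies a series by each positive constant in `multipliers`, recomputes
#' `beta`, and reports the maximum absolute deviation from the unscaled
#' `beta`. For the default log-linear method the deviation is zero to machine
#' precision: multiplying `Y` by `c` shifts `log(Y)` by the constant `log(c)`,
#' which changes only the OLS intercept (hence `alpha`), never the slope.
#'
#' @inheritParams fit_exponential
#' @param multipliers Vector of positive constants.
#' @return Maximum of `|beta(c * Y) - beta(Y)|` over the multipliers.
#' @export
check_scale_invariance <- function(data, multipliers = c(0.5, 2, 10),
                                   method = c("log_linear", "nls")) {
  method <- match.arg(method)
  if (any(multipliers <= 0)) abort("`multipliers` must be positive")
  beta0 <- detriment_index(data, method = method)$beta
  devs <- purrr::map_dbl(multipliers, function(c) {
    scaled <- dplyr::mutate(
      data,
      annual_count = .data$annual_count * c,
      cumulative_count = .data$cumulative_count * c
    )
    abs(detriment_index(scaled, method = method)$beta - beta0)
  })
  max(devs)
}

#' Normalise ADR counts by drug exposure
#'
#' Divides each annual report count by that year's exposure (doses sold or a
#' similar usage proxy) and recomputes the cumulative curve from the resulting
#' rates, so that cross-drug comparisons reflect per-use risk rather than raw
#' reporting volume. Downstream fitting and ranking work unchanged on the
#' rate-valued series. Constant exposure leaves the Detriment Index `beta`
#' untouched (it only rescales the series).
#'
#' @param data Series tibble (possibly multi-drug) from
#'   [read_annual_counts()].
#' @param exposure Data frame or CSV path with columns `drug`, `year`,
#'   `exposure_units` (positive); must cover every `(drug, year)` in `data`.
#' @return `data` with `annual_count` and `cumulative_count` replaced by
#'   reporting rates (reports per exposure unit).
#' @examples
#' s <- tibble::tibble(drug = "Test", year = 2001:2006,
#'                     count = c(10, 12, 15, 18, 22, 23))
#' s <- read_annual_counts(s)
#' exp_tbl <- tibble::tibble(drug = "Test", year = 2001:2006,
#'                           exposure_units = 1000)
#' normalize_by_exposure(s, exp_tbl)
#' @export
normalize_by_exposure <- function(data, exposure) {
  stopifnot(is.data.frame(data))
  exposure <- read_table_arg(exposure, "exposure")
  required <- c("drug", "year", "exposure_units")
  missing_cols <- setdiff(required, names(exposure))
  if (length(missing_cols) > 0) {
    abort(paste0("`exposure` lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(exposure$exposure_units <= 0 | is.na(exposure$exposure_units))) {
    abort("`exposure_units` must be positive for every row")
  }
  joined <- dplyr::left_join(
    data, exposure[, required],
    by = c("drug", "year")
  )
  if (anyNA(joined$exposure_units)) {
    miss <- joined[is.na(joined$exposure_units), c("drug", "year")]
    abort(paste0(
      "exposure missing for: ",
      paste(paste0(miss$drug, ":", miss$year), collapse = ", ")
    ))
  }
  joined |>
    dplyr::mutate(annual_count = .data$annual_count / .data$exposure_units) |>
    dplyr::mutate(cumulative_count = cumsum(.data$annual_count),
                  .by = "drug") |>
    dplyr::select(-"exposure_units")
}

#' Rank a panel of drugs by the Detriment Index
#'
#' Computes `beta` for every drug and returns the panel sorted ascending in
#' `beta`: rank 1 is the smallest growth rate, i.e. the slowest-accumulating
#' safety signal and the most favourable profile. Ties share the minimum
#' rank. Per-drug fitting failures are reported in the `error` column (with
#' `NA` rank) rather than aborting the panel.
#'
#' @param data Multi-drug series tibble, or a precomputed [detriment_index()]
#'   table (recognised by its `beta` column).
#' @inheritParams detriment_index
#' @return Tibble with columns `rank`, `drug`, `beta`, `beta_lo`, `beta_hi`,
#'   `r2`, `alpha` (plus `composite` when requested and `error`), sorted
#'   ascending by `beta`.
#' @export
rank_drugs <- function(data, method = c("log_linear", "nls"),
                       composite = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) abort("empty panel: nothing to rank")

  if ("beta" %in% names(data)) {
    res <- tibble::as_tibble(data)
    if (!"error" %in% names(res)) res$error <- NA_character_
  } else {
    if (!"drug" %in% names(data)) abort("`data` must have a `drug` column")
    res <- data |>
      dplyr::group_split(.data$drug) |>
      purrr::map(function(d) {
        out <- tryCatch(
          detriment_index(d, method = method, composite = composite),
          error = function(e) tibble::tibble(
            drug = d$drug[1], beta = NA_real_, beta_lo = NA_real_,
            beta_hi = NA_real_, alpha = NA_real_, r2 = NA_real_,
            flat = NA, error = conditionMessage(e)
          )
        )
        if (!"error" %in% names(out)) out$error <- NA_character_
        out
      }) |>
      dplyr::bind_rows()
  }

  res$rank <- NA_integer_
  ok <- !is.na(res$beta)
  res$rank[ok] <- as.integer(rank(res$beta[ok], ties.method = "min"))
  cols <- c("rank", "drug", "beta", "beta_lo", "beta_hi", "r2", "alpha",
            if (composite) "composite", "error")
  res |>
    dplyr::arrange(.data$beta) |>
    dplyr::select(dplyr::any_of(cols))
}

#' Experimental composite index: beta weighted by cumulative burden
#'
#' An exploratory variant of the Detriment Index that multiplies `beta` by the
#' normalised area under the cumulative curve,
#' `trapezoid(Y) / (n * max(Y))`, so that the score reflects both the speed
#' (`beta`) and the relative magnitude of signal accumulation. The
#' normalisation makes the AUC factor scale invariant, so the composite
#' inherits `beta`'s invariance to reporting volume. This index is
#' experimental: its weighting is a design choice of this package, it is not
#' the Detriment Index, and it is never used for default ranking.
#'
#' @inheritParams fit_exponential
#' @return A single number; 0 for an all-zero series. Shares `beta`'s sign.
#' @export
composite_index <- function(data, method = c("log_linear", "nls")) {
  method <- match.arg(method)
  v <- series_vectors(data)
  beta <- detriment_index(data, method = method)$beta
  m <- max(v$y)
  if (m == 0) {
    return(0)
  }
  auc <- trapezoid_area(v$t, v$y)
  beta * auc / (length(v$y) * m)
}

# Trapezoidal rule on an irregular grid.
trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
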