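#' Classify the temporal pattern of one cumulative ADR curve
#'
#' Fits all four growth families (linear, exponential, shifted
#' Michaelis-Menten saturation, logistic) to a single drug's cumulative curve
#' and assigns one of the four pattern labels — `saturation`, `linear`,
#' `exponential`, `sigmoidal` — or `undetermined` when no family yields a
#' valid fit. Selection is by minimum AIC among valid fits with a parsimony
#' tie rule: when the top candidates are within `tie_delta` AIC units of the
#' minimum, the family with the fewest parameters wins, and remaining ties are
#' broken by the fixed precedence linear, exponential, saturation, logistic
#' (simpler, monotone-growth families first). Families that fail to converge
#' or violate their parameter constraints (`theta2 <= 0`, `k <= 0`) are
#' excluded rather than failing the drug. The procedure is deterministic: the
#' same series always yields the same label.
#'
#' For classification the exponential family is fitted by `nls` (initialised
#' from the log-linear solution), not by the log-linear default used for the
#' Detriment Index: AIC compares residual sums of squares, so every candidate
#' must minimise least squares on the same (original cumulative) scale or the
#' comparison is biased against the exponential family.
#'
#' @inheritParams fit_linear
#' @param tie_delta AIC difference below which models are treated as tied
#'   (default 2).
#' @param method Exponential fitting method passed to [fit_exponential()];
#'   `"nls"` by default (see Details).
#' @return A `pattern_classification` object: list with `drug_id`, `label`,
#'   `scores` (per-family tibble of AIC/BIC/R2/RMSE/validity/delta-AIC),
#'   `best_fit` (the winning `growth_fit`) and `fits` (all four attempts).
#'   Use [tidy()] for the score table and [glance()] for a one-row summary.
#' @examples
#' s <- simulate_series("logistic", list(L = 1e5, k = 0.55, t0 = 5.75),
#'                      n_years = 25)
#' classify_pattern(s)
#' @export
classify_pattern <- function(data, tie_delta = 2, method = "nls") {
  v <- series_vectors(data)
  if (length(v$y) < 6) {
    abort("classification needs at least 6 observations")
  }
  if (tie_delta < 0) abort("`tie_delta` must be non-negative")

  fits <- purrr::map(names(FAMILIES), function(fam) {
    tryCatch(
      suppressWarnings(fit_growth(data, family = fam, method = method)),
      error = function(e) structure(
        list(family = fam, drug_id = v$drug, valid = FALSE,
             flags = "fit_error", error = conditionMessage(e),
             aic = NA_real_, bic = NA_real_, r2 = NA_real_,
             rmse = NA_real_, n_params = N_PARAMS[[fam]]),
        class = "failed_fit"
      )
    )
  })
  names(fits) <- names(FAMILIES)

  scores <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      family = f$family, n_params = as.integer(f$n_params),
      aic = f$aic, bic = f$bic, r2 = f$r2, rmse = f$rmse,
      valid = isTRUE(f$valid)
    )
  })

  valid <- scores$valid
  # A numerically perfect fit (RSS negligible relative to the series' total
  # variation) is treated as AIC -Inf so that e.g. an exact straight line and
  # its rss = 0 saturation special case compete on parameter count, not on
  # floating-point residual dust.
  tss <- max(sum((v$y - mean(v$y))^2), 1)
  perfect <- purrr::map_lgl(fits, function(f) {
    inherits(f, "growth_fit") && f$valid && f$rss <= 1e-10 * tss
  })
  scores$aic[perfect] <- -Inf
  scores$bic[perfect] <- -Inf
  if (sum(valid) < 2) {
    if (sum(valid) == 0) {
      scores$delta_aic <- NA_real_
      return(new_pattern_classification(v$drug, "undetermined", scores,
                                        NULL, fits))
    }
    # A single valid family still yields a label, but flag the thin evidence.
  }

  aic <- ifelse(valid, scores$aic, Inf)
  best_aic <- min(aic)
  delta <- if (is.infinite(best_aic) && best_aic < 0) {
    # Perfect fits: zero for every perfect fit, infinite for the rest.
    ifelse(aic == -Inf, 0, Inf)
  } else {
    aic - best_aic
  }
  scores$delta_aic <- ifelse(valid, delta, NA_real_)

  cand <- which(valid & delta < tie_delta)
  if (length(cand) == 0) cand <- which.min(aic)
  cand <- cand[scores$n_params[cand] == min(scores$n_params[cand])]
  if (length(cand) > 1) {
    prec <- match(names(FAMILIES)[cand], FAMILY_PRECEDENCE)
    cand <- cand[which.min(prec)]
  }
  winner_fam <- names(FAMILIES)[cand]
  new_pattern_classification(v$drug, FAMILIES[[winner_fam]], scores,
                             fits[[winner_fam]], fits)
}

new_pattern_classification <- function(drug, label, scores, best_fit, fits) {
  structure(
    list(drug_id = drug, label = label, scores = scores,
         best_fit = best_fit, fits = fits),
    class = "pattern_classification"
  )
}

#' @export
print.pattern_classification <- function(x, ...) {
  cat("<pattern_classification>", x$drug_id, "->", x$label, "\n")
  print(x$scores)
  invisible(x)
}

#' Classify every drug in a panel
#'
#' Applies [classify_pattern()] to each drug in a multi-drug series table.
#' Failures (e.g. series too short) are isolated per drug: the drug appears in
#' the output with label `undetermined` and its error message, and never
#' aborts the rest of the panel.
#'
#' @param data Multi-drug series tibble (as from [read_annual_counts()]).
#' @param ... Passed to [classify_pattern()].
#' @return Tibble with one row per drug: `drug`, `label`, `aic_linear`,
#'   `aic_exponential`, `aic_saturation`, `aic_logistic`, `delta_aic_winner`
#'   (AIC gap between the winner and the runner-up), `r2_winner`, `error`.
#' @export
classify_panel <- function(data, ...) {
  stopifnot(is.data.frame(data))
  if (!"drug" %in% names(data)) abort("`data` must have a `drug` column")
  empty <- tibble::tibble(
    drug = character(), label = character(),
    aic_linear = numeric(), aic_exponential = numeric(),
    aic_saturation = numeric(), aic_logistic = numeric(),
    delta_aic_winner = numeric(), r2_winner = numeric(),
    error = character()
  )
  if (nrow(data) == 0) {
    return(empty)
  }
  rows <- data |>
    dplyr::group_split(.data$drug) |>
    purrr::map(function(d) {
      drug <- d$drug[1]
      cl <- tryCatch(classify_pattern(d, ...), error = function(e) e)
      if (inherits(cl, "error")) {
        return(tibble::tibble(
          drug = drug, label = "undetermined",
          aic_linear = NA_real_, aic_exponential = NA_real_,
          aic_saturation = NA_real_, aic_logistic = NA_real_,
          delta_aic_winner = NA_real_, r2_winner = NA_real_,
          error = conditionMessage(cl)
        ))
      }
      g <- glance(cl)
      g$error <- NA_character_
      g
    })
  dplyr::bind_rows(empty, rows)
}
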