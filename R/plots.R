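#' Plot cumulative ADR curves
#'
#' Cumulative report counts over calendar years, one line per drug.
#'
#' @param data Series tibble from [read_annual_counts()] or
#'   [simulate_series()].
#' @param log_y Use a log10 y axis (useful when comparing drugs whose
#'   reporting volumes differ by orders of magnitude).
#' @return A ggplot object.
#' @export
plot_series <- function(data, log_y = FALSE) {
  stopifnot(is.data.frame(data))
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(.data$year, .data$cumulative_count, colour = .data$drug)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = "Cumulative ADR reports", colour = NULL)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a fitted growth curve over the observations
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed cumulative counts (points) with the
#'   fitted curve evaluated on a fine time grid (line).
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  obs <- augment(object)
  tg <- seq(min(object$t), max(object$t), length.out = 200)
  curve <- tibble::tibble(
    t = tg,
    y = growth_curve(object$family, object$params, tg)
  )
  ggplot2::ggplot(obs, ggplot2::aes(.data$t, .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$t, .data$y),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "Years since series start", y = "Cumulative ADR reports",
      title = paste0(object$drug_id, ": ", object$family, " fit (R² = ",
                     signif(object$r2, 3), ")")
    )
}

#' Plot all candidate family fits behind a classification
#'
#' @param object A `pattern_classification`.
#' @param ... Unused.
#' @return A ggplot object: the observed curve with one fitted line per valid
#'   family; the winning family is named in the title.
#' @exportS3Method ggplot2::autoplot
autoplot.pattern_classification <- function(object, ...) {
  fits <- purrr::keep(object$fits, \(f) inherits(f, "growth_fit") && f$valid)
  if (length(fits) == 0) abort("no valid fits to plot")
  obs <- augment(fits[[1]])
  tg <- seq(min(obs$t), max(obs$t), length.out = 200)
  curves <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      t = tg, y = growth_curve(f$family, f$params, tg),
      family = FAMILIES[[f$family]]
    )
  })
  ggplot2::ggplot(obs, ggplot2::aes(.data$t, .data$observed)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$t, .data$y, colour = .data$family)
    ) +
    ggplot2::labs(
      x = "Years since series start", y = "Cumulative ADR reports",
      colour = "Family",
      title = paste0(object$drug_id, ": pattern = ", object$label)
    )
}

#' Plot a Detriment-Index ranking
#'
#' @param ranking Output of [rank_drugs()].
#' @return A ggplot object: drugs ordered by `beta` with 95% intervals.
#' @export
plot_ranking <- function(ranking) {
  stopifnot(is.data.frame(ranking), "beta" %in% names(ranking))
  d <- ranking[!is.na(ranking$beta), ]
  d$drug <- stats::reorder(d$drug, -d$beta)
  ggplot2::ggplot(d, ggplot2::aes(.data$beta, .data$drug)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$beta_lo, xmax = .data$beta_hi)
    ) +
    ggplot2::labs(
      x = expression("Detriment Index " * beta * " (per year)"), y = NULL
    )
}
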