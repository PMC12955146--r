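#' Bundled oncology example panel
#'
#' Fitted exponential parameters (`alpha`, `beta`) for fifteen widely used
#' oncology drugs, as published for their cumulative ADR reporting curves on
#' the public pharmacovigilance dashboards. `oncology_panel_params()` returns
#' the parameter table; `oncology_panel_series()` regenerates noise-free
#' cumulative series from those parameters — a convenient worked example for
#' [rank_drugs()] that does not require any dashboard download. These are
#' published fitted parameters used as a fixture; the raw report counts are
#' not redistributed.
#'
#' @return `oncology_panel_params()`: tibble with `drug`, `alpha`, `beta`,
#'   `n_years`. `oncology_panel_series()`: multi-drug series tibble (one
#'   noise-free exponential curve per drug, `t = 1..n_years`).
#' @examples
#' rank_drugs(oncology_panel_series())
#' @export
oncology_panel_params <- function() {
  path <- system.file("extdata", "oncology_panel_params.csv",
                      package = "adrtrend", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname oncology_panel_params
#' @export
oncology_panel_series <- function() {
  oncology_panel_params() |>
    purrr::pmap(function(drug, alpha, beta, n_years) {
      simulate_series(
        "exponential", list(alpha = alpha, beta = beta),
        n_years = n_years, drug_id = drug
      )
    }) |>
    dplyr::bind_rows()
}
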