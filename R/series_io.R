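#' Read annual ADR report counts into tidy cumulative series
#'
#' Reads a long-format table of annual adverse drug reaction (ADR) report
#' counts — one row per `(drug, year)` as exported from dashboards such as
#' FAERS or VigiAccess — and builds one cumulative reporting series per drug.
#' Rows sharing the same `(drug, year)` (e.g. from merged export files) are
#' summed; missing interior years are filled with a count of zero so that each
#' drug's series sits on a consecutive annual grid; cumulative counts and a
#' 1-based time index (years since the first observed year) are computed.
#'
#' @param source A data frame with columns `drug`, `year`, `count`
#'   (`annual_count` is accepted in place of `count`, so written series
#'   round-trip), or the path to a CSV file with those columns.
#' @param metadata Optional data frame or CSV path with columns `drug`,
#'   `withdrawal_status`, `withdrawal_year` to join onto the result.
#'
#' @return A tibble with columns `drug`, `year`, `time_index`, `annual_count`,
#'   `cumulative_count` (plus withdrawal columns when `metadata` is supplied),
#'   ordered by drug then year. An empty input yields an empty tibble.
#' @examples
#' counts <- tibble::tibble(
#'   drug = "X", year = c(2000, 2003), count = c(2, 1)
#' )
#' read_annual_counts(counts)
#' @export
read_annual_counts <- function(source, metadata = NULL) {
  df <- read_table_arg(source, "source")
  if (!"count" %in% names(df) && "annual_count" %in% names(df)) {
    df <- dplyr::rename(df, count = "annual_count")
  }
  required <- c("drug", "year", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`source` must have columns drug, year, count; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  keep_meta <- intersect(c("withdrawal_status", "withdrawal_year"), names(df))
  df <- df[, c(required, keep_meta)]

  if (nrow(df) == 0) {
    return(tibble::tibble(
      drug = character(), year = integer(), time_index = integer(),
      annual_count = numeric(), cumulative_count = numeric()
    ))
  }

  validate_counts_cols(df)
  df$year <- as.integer(df$year)

  out <- df |>
    dplyr::summarise(
      count = sum(.data$count),
      .by = c("drug", "year")
    ) |>
    dplyr::group_by(.data$drug) |>
    dplyr::group_modify(\(d, key) {
      grid <- tibble::tibble(year = seq(min(d$year), max(d$year)))
      d <- dplyr::left_join(grid, d, by = "year") |>
        dplyr::mutate(count = tidyr::replace_na(.data$count, 0)) |>
        dplyr::arrange(.data$year)
      tibble::tibble(
        year = d$year,
        time_index = seq_len(nrow(d)),
        annual_count = d$count,
        cumulative_count = cumulate(d$count)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$drug, .data$year)

  if (length(keep_meta) > 0) {
    meta_df <- unique(df[, c("drug", keep_meta)])
    out <- dplyr::left_join(out, meta_df, by = "drug")
  }
  if ("withdrawal_year" %in% names(out)) {
    out$withdrawal_year <- as.integer(out$withdrawal_year)
  }
  if (!is.null(metadata)) {
    meta <- read_table_arg(metadata, "metadata")
    if (!"drug" %in% names(meta)) {
      abort("`metadata` must have a `drug` column")
    }
    out <- dplyr::left_join(out, meta, by = "drug")
  }
  out
}

#' Cumulate annual counts
#'
#' Running total (prefix sum) of a vector of non-negative annual counts: the
#' cumulative ADR curve that all growth models in this package are fitted to.
#'
#' @param annual_counts Numeric vector of non-negative annual counts.
#' @return Numeric vector of the same length; element `i` is the sum of the
#'   first `i` annual counts, so the result is non-decreasing.
#' @examples
#' cumulate(c(1, 2, 3))
#' @export
cumulate <- function(annual_counts) {
  if (!is.numeric(annual_counts)) {
    abort("`annual_counts` must be numeric")
  }
  if (anyNA(annual_counts)) {
    abort("`annual_counts` must not contain missing values")
  }
  if (any(annual_counts < 0)) {
    bad <- which(annual_counts < 0)[1]
    abort(paste0("negative annual count at position ", bad))
  }
  cumsum(annual_counts)
}

#' Write one or more ADR series to CSV
#'
#' Writes the tidy series table produced by [read_annual_counts()] or
#' [simulate_series()] as comma-delimited UTF-8 with columns `drug`, `year`,
#' `annual_count`, `cumulative_count` (withdrawal metadata columns are
#' preserved when present). Reading the file back with [read_annual_counts()]
#' reproduces the series.
#'
#' @param data Series tibble (columns `drug`, `year`, `annual_count`; other
#'   columns except `time_index` and `cumulative_count` are carried through).
#' @param path Destination file path.
#' @return `data`, invisibly, so the call can sit inside a pipe.
#' @export
write_series <- function(data, path) {
  stopifnot(is.data.frame(data))
  required <- c("drug", "year", "annual_count")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"cumulative_count" %in% names(data)) {
    data <- data |>
      dplyr::mutate(cumulative_count = cumulate(.data$annual_count), .by = "drug")
  }
  cols <- c(
    "drug", "year", "annual_count", "cumulative_count",
    intersect(c("withdrawal_status", "withdrawal_year"), names(data))
  )
  readr::write_csv(data[, cols], path)
  invisible(data)
}

# Accept a data frame or a CSV path.
read_table_arg <- function(x, arg) {
  if (is.data.frame(x)) {
    return(tibble::as_tibble(x))
  }
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort(paste0("file not found: ", x))
    }
    return(readr::read_csv(x, show_col_types = FALSE))
  }
  abort(paste0("`", arg, "` must be a data frame or a file path"))
}

validate_counts_cols <- function(df) {
  if (anyNA(df$year) || any(df$year != round(df$year))) {
    bad <- which(is.na(df$year) | df$year != round(df$year))[1]
    abort(paste0("non-integer year in row ", bad))
  }
  # Dashboard exports carry integer counts, but exposure-normalised rates and
  # model-valued simulated curves are legitimate non-integer series; only
  # negative or missing counts are rejected.
  if (anyNA(df$count) || any(df$count < 0)) {
    bad <- which(is.na(df$count) | df$count < 0)[1]
    abort(paste0(
      "negative or missing count in row ", bad,
      " (drug ", df$drug[bad], ", year ", df$year[bad], ")"
    ))
  }
  invisible(df)
}

# Extract (drug_id, t, y) from a single-drug series tibble; shared by all
# fitters. Errors if more than one drug is present.
series_vectors <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"cumulative_count" %in% names(data)) {
    abort("`data` must have a `cumulative_count` column (see read_annual_counts())")
  }
  drug <- if ("drug" %in% names(data)) unique(data$drug) else "series"
  if (length(drug) > 1) {
    abort(paste0(
      "`data` contains ", length(drug),
      " drugs; fit one drug at a time (see classify_panel()/rank_drugs() for panels)"
    ))
  }
  t <- if ("time_index" %in% names(data)) data$time_index else seq_len(nrow(data))
  ord <- order(t)
  list(drug = drug, t = as.numeric(t[ord]), y = as.numeric(data$cumulative_count[ord]))
}
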