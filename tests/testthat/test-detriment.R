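test_that("the Detriment Index is the exponential growth rate, 0 for flat series", {
  s <- simulate_series("exponential", list(alpha = 1198.5, beta = 0.0972),
                       n_years = 30, drug_id = "Tamoxifen")
  d <- detriment_index(s)
  expect_equal(d$beta, 0.0972, tolerance = 1e-8)
  expect_equal(d$alpha, 1198.5, tolerance = 1e-6)
  expect_true(d$beta_lo <= d$beta & d$beta <= d$beta_hi)

  flat <- make_series(c(7, rep(0, 9)), drug = "flat")
  df <- detriment_index(flat)
  expect_equal(df$beta, 0)
  expect_true(df$flat)

  doubled <- dplyr::mutate(
    s,
    annual_count = annual_count * 2, cumulative_count = cumulative_count * 2
  )
  expect_equal(detriment_index(doubled)$beta, d$beta, tolerance = 1e-13)
})

test_that("beta is invariant to positive rescaling", {
  s <- simulate_series("exponential", list(alpha = 50, beta = 0.2), 20,
                       noise = "poisson_increments", seed = 9)
  expect_lt(check_scale_invariance(s, c(2, 10, 0.5)), 1e-12)
  expect_equal(check_scale_invariance(s, 1), 0)
  # nls route is invariant to optimizer tolerance
  expect_lt(check_scale_invariance(s, c(2, 0.5), method = "nls"), 1e-8)
})

test_that("exposure normalisation turns counts into per-use rates", {
  counts <- read_annual_counts(tibble::tibble(
    drug = c("Test", "Reference"), year = 2000, count = c(100, 50)
  ))
  exposure <- tibble::tibble(
    drug = c("Test", "Reference"), year = 2000, exposure_units = c(1000, 100)
  )
  rates <- normalize_by_exposure(counts, exposure)
  expect_equal(rates$annual_count[rates$drug == "Test"], 0.1)
  expect_equal(rates$annual_count[rates$drug == "Reference"], 0.5)

  s <- make_series(c(10, 12, 15, 18, 22), drug = "D")
  unit <- tibble::tibble(drug = "D", year = 2000:2004, exposure_units = 1)
  expect_equal(normalize_by_exposure(s, unit), s)

  # scaling every exposure by c divides every rate by c
  e1 <- tibble::tibble(drug = "D", year = 2000:2004,
                       exposure_units = c(10, 20, 40, 40, 50))
  e2 <- dplyr::mutate(e1, exposure_units = exposure_units * 4)
  r1 <- normalize_by_exposure(s, e1)
  r2 <- normalize_by_exposure(s, e2)
  expect_equal(r2$annual_count, r1$annual_count / 4)
  expect_equal(r2$cumulative_count, r1$cumulative_count / 4)

  expect_error(
    normalize_by_exposure(s, e1[-2, ]),
    "exposure missing for: D:2001"
  )
  expect_error(
    normalize_by_exposure(s, dplyr::mutate(e1, exposure_units = 0)),
    "positive"
  )
})

test_that("constant exposure never changes beta", {
  s <- simulate_series("exponential", list(alpha = 30, beta = 0.25), 15,
                       noise = "poisson_increments", seed = 12)
  e <- tibble::tibble(drug = "sim", year = s$year, exposure_units = 250)
  expect_equal(detriment_index(normalize_by_exposure(s, e))$beta,
               detriment_index(s)$beta, tolerance = 1e-12)
})

test_that("ranking sorts ascending in beta with shared ranks for ties", {
  single <- rank_drugs(simulate_series("exponential", list(alpha = 5, beta = 0.3),
                                       10, drug_id = "only"))
  expect_equal(single$rank, 1L)

  withr::with_seed(40, {
    betas <- sample(seq(0.05, 0.9, length.out = 12))
  })
  panel <- purrr::imap_dfr(betas, function(b, i) {
    simulate_series("exponential", list(alpha = 20, beta = b), 15,
                    drug_id = paste0("d", i))
  })
  r <- rank_drugs(panel)
  expect_equal(r$drug, paste0("d", order(betas)))
  expect_equal(r$rank, seq_along(betas))

  # exact ties share the minimum rank (precomputed-results path)
  tied <- tibble::tibble(
    drug = c("a", "b", "c"), beta = c(0.2, 0.2, 0.4),
    beta_lo = c(0.19, 0.19, 0.39), beta_hi = c(0.21, 0.21, 0.41),
    r2 = 1, alpha = c(10, 99, 10)
  )
  rt <- rank_drugs(tied)
  expect_equal(rt$rank, c(1L, 1L, 3L))

  # ranking is invariant to per-drug rescaling
  rescaled <- panel |>
    dplyr::mutate(
      annual_count = annual_count * as.numeric(factor(drug)),
      cumulative_count = cumulative_count * as.numeric(factor(drug))
    )
  expect_equal(rank_drugs(rescaled)$drug, r$drug)

  expect_error(rank_drugs(panel[0, ]), "empty panel")
})

test_that("per-drug ranking failures are reported, not fatal", {
  panel <- dplyr::bind_rows(
    simulate_series("exponential", list(alpha = 10, beta = 0.3), 12, drug_id = "ok"),
    make_series(c(0, 1, 2), drug = "too_short")
  )
  r <- suppressWarnings(rank_drugs(panel))
  expect_equal(nrow(r), 2)
  expect_true(is.na(r$beta[r$drug == "too_short"]))
  expect_false(is.na(r$error[r$drug == "too_short"]))
  expect_equal(r$rank[r$drug == "ok"], 1L)
})

test_that("experimental composite index shares beta's sign and scale invariance", {
  zero <- make_series(rep(0, 8), drug = "none")
  expect_equal(composite_index(zero), 0)

  s <- simulate_series("exponential", list(alpha = 50, beta = 0.2), 20,
                       noise = "poisson_increments", seed = 9)
  ci <- composite_index(s)
  expect_gt(ci, 0)
  doubled <- dplyr::mutate(
    s,
    annual_count = annual_count * 2, cumulative_count = cumulative_count * 2
  )
  expect_equal(composite_index(doubled), ci, tolerance = 1e-12)

  # normalised AUC factor matches the pracma trapezoid oracle
  v <- s$cumulative_count
  auc_oracle <- pracma::trapz(s$time_index, v) / (length(v) * max(v))
  expect_equal(ci, detriment_index(s)$beta * auc_oracle, tolerance = 1e-12)

  shrinking <- make_cumulative_series(100 * exp(-0.1 * (1:12)))
  expect_lt(composite_index(shrinking), 0)
})
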