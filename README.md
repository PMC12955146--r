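# adrtrend

Trend-based pharmacovigilance on annual adverse drug reaction (ADR) report
counts. `adrtrend` takes the long-format count tables exported by public
spontaneous-reporting dashboards (FAERS, VigiAccess), builds each drug's
cumulative reporting curve, fits four growth families to it, classifies the
temporal pattern, and ranks drugs by how fast their safety signal
accumulates.

It is aimed at pharmacovigilance analysts and drug-safety researchers who
want a reproducible, scale-free way to compare long-term reporting
behaviour across drugs — including drugs already withdrawn from the market,
whose reporting often continues for years.

## The model

For a cumulative report count $Y(t)$ over years $t = 1..n$, four candidate
mean functions are fitted by least squares:

- linear: $Y = a + bt$
- exponential: $Y = \alpha e^{\beta t}$
- saturation (shifted Michaelis–Menten): $Y = Y_0 + \theta_1 t/(\theta_2 + t)$
- logistic: $Y = L / (1 + e^{-k(t - t_0)})$

The pattern label (linear / exponential / saturation / sigmoidal) is chosen
by minimum AIC, with a parsimony tie rule at $\Delta\mathrm{AIC} < 2$.

The **Detriment Index** is $\beta$, the exponential growth rate per year,
estimated by default through log-linear OLS. Multiplying every count by a
positive constant changes only $\alpha$, never $\beta$, so $\beta$ ranks
drugs on one scale regardless of reporting volume: higher $\beta$, faster
signal accumulation, less favourable profile. Exposure normalisation
(reports per dose sold) and an explicitly experimental $\beta\times$AUC
composite are provided alongside.

A seeded simulator generates series from any of the four families with
Poisson count noise, Gaussian noise, or post-withdrawal reporting spikes,
and drives built-in parameter-recovery and classification-accuracy studies.

## Worked example

```r
library(adrtrend)

# fifteen oncology drugs, noise-free curves regenerated from their
# published fitted exponential equations (bundled fixture)
ranking <- rank_drugs(oncology_panel_series())
head(ranking, 3)
#> # A tibble: 3 × 8
#>    rank drug        beta beta_lo beta_hi    r2 alpha error
#>   <int> <chr>      <dbl>   <dbl>   <dbl> <dbl> <dbl> <chr>
#> 1     1 Tamoxifen 0.0972  0.0972  0.0972     1 1199. <NA>
#> 2     2 Avastin   0.121   0.121   0.121      1 2216. <NA>
#> 3     3 Bleomycin 0.139   0.139   0.139      1  115. <NA>
```

Rank 1 (smallest $\beta$, here Tamoxifen at 0.0972 per year) is the drug
whose ADR reports accumulate slowest — the most favourable long-term
profile in the panel; the last rank (Pembrolizumab, $\beta = 0.8277$) is
the fastest-accumulating signal.

Classification of a single curve:

```r
s <- simulate_series("logistic", list(L = 1e5, k = 0.5513, t0 = 5.7469),
                     n_years = 25, noise = "poisson_increments", seed = 1)
cl <- classify_pattern(s)
cl$label
#> [1] "sigmoidal"
glance(cl)[, c("label", "aic_logistic", "aic_saturation", "r2_winner")]
#> # A tibble: 1 × 4
#>   label     aic_logistic aic_saturation r2_winner
#>   <chr>            <dbl>          <dbl>     <dbl>
#> 1 sigmoidal         197.           455.     1.000
```

Everything is a tibble in, tibble out: `read_annual_counts()` →
`classify_panel()` / `rank_drugs()` pipe together, fitted objects have
`tidy()`, `glance()`, `augment()` and `autoplot()` methods, and a thin
command-line front end (`inst/cli/adrtrend.R`, subcommands `ingest`,
`fit`, `classify`, `rank`, `simulate`, `study`) wraps the same functions
for shell pipelines.

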