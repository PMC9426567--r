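# cocultr

Growth kinetics, dose-response and population-ratio analysis for two-color
bacterial cocultures.

## What this package is for

Mixed cultures of fluorescently marked bacterial strains — for example a
cobamide-salvaging *E. coli* strain cocultured with a cobamide-dependent
partner — are commonly followed in two complementary ways:

1. **Plate-reader deconvolution.** A multiwell reader records absorbance at
   600 nm plus CFP- and YFP-like fluorescence every few minutes.  Because
   each strain carries its own marker, the fluorescence channels resolve the
   growth of each subpopulation inside the mixture, once fluorescence has
   been calibrated against absorbance using single-marker control wells.
2. **Serial-transfer cytometry.** Cultures diluted 1:100 into fresh medium
   every 24 h are sampled by flow cytometry (FITC and AmCyan channels,
   10^5 events per sample), and threshold gating turns event counts into
   salvager:dependent population ratios, tracked over many transfers with
   transfer-specific detection limits derived from blank samples.

`cocultr` implements the full quantitative chain for both assays, plus a
synthetic-data generator with known ground truth so that every stage can be
validated by parameter recovery.

### The methods at the core

* **Abundance extraction.** Raw fluorescence is converted to
  absorbance-equivalents via replicate-averaged calibration slopes fitted in
  the linear range (raw OD 0–0.3 by default), pathlength-corrected into
  *bacterial units* (1 b.u. = blank-corrected OD600 of 1), and
  blank-corrected (well-specific for absorbance, global non-marker-well
  means for fluorescence).
* **Rate, lag, yield.** Trajectories are smoothed with a centered 7-point
  rolling mean and truncated to 24 or 60 h.  The growth rate is a
  **Theil-Sen** estimator (median of all pairwise slopes) on log abundances
  within either a fixed abundance band (1.5×10⁻² – 6×10⁻² b.u.) or a
  dynamic window ending where the 19-point rolling rate last exceeds
  0.1 h⁻¹; fewer than 7 in-window points force rate 0.  Lag time is the
  back-extrapolation of the fit to the known inoculum
  (`lag = (ln a₀ − intercept)/rate`, −∞ for non-growers); yield is the
  smoothed abundance at 24 h.
* **Dose-response.** Responses y(x) follow the four-parameter logistic
  y = y_bottom + xⁿ (y_top − y_bottom)/(xⁿ + EC50ⁿ), fitted by
  Levenberg-Marquardt on log10 EC50, with t-based EC50 confidence intervals
  (df = N − 4) and two-tailed t-tests for EC50 differences
  (df = N₁ + N₂ − 8).
* **Cytometry ratios.** Events are gated with the standard thresholds
  (YFP⁺CFP⁻: FITC > 10³ & AmCyan < 4×10³; YFP⁻CFP⁺: FITC < 7×10² &
  AmCyan > 2×10³; YFP⁻CFP⁻: FITC < 10³ & AmCyan < 2×10³; residual
  YFP⁺CFP⁺), with a transfer-zero variant (AmCyan split at 5×10³).  Ratios
  are YNCP/YPCN counts; detection limits per transfer are
  max(blank_YNCP, 1)/10⁵ and 10⁵/max(blank_YPCN, 1).  Long-term competition
  is summarized by OLS slopes of log10(ratio) per transfer, compared by
  t-tests (df = n₁ + n₂ − 4) under Holm-Bonferroni correction (α = 0.05).

## Worked example

Simulate the canonical two-strain experiment — a salvager (CFP, 0.47 h⁻¹,
no lag) with a dependent (YFP, 0.40 h⁻¹, 4 h lag, one-tenth the yield) —
and run the full deconvolution pipeline:

```r
library(cocultr)

sal <- strain_params("Sal", 0.47, lag = 0, initial_abundance = 5e-3,
                     yield_cap = 0.55, marker = "CFP")
dep <- strain_params("Dep", 0.40, lag = 4, initial_abundance = 5e-3,
                     yield_cap = 0.055, marker = "YFP")
plate <- simulate_coculture_plate(list(sal, dep), noiseless_readout(), seed = 1)
fits <- run_growth_pipeline(plate$readings, plate$metadata)$fits
dplyr::filter(fits, well == "A1")
#> # A tibble: 3 × 9
#>   well  channel strain   rate intercept   lag_h yield_24h window_mode n_points_used
#>   <chr> <chr>   <chr>   <dbl>     <dbl>   <dbl>     <dbl> <chr>               <int>
#> 1 A1    A600    NA      0.452     -5.05  0.995      0.605 dynamic                54
#> 2 A1    CFP     Sal     0.470     -5.29 -0.0260     0.55  dynamic                49
#> 3 A1    YFP     Dep     0.400     -6.89  3.98       0.055 dynamic                22
```

The fluorescence channels recover each strain's rate exactly (0.470 and
0.400 h⁻¹), the dependent's 4 h lag to within one 10-min sampling interval,
and the 10:1 yield ratio (0.55/0.055 b.u.); the absorbance channel reports
the mixture total, a blend of the two.

Dose-response fitting works the same way from a tidy table:

```r
doses <- 10^seq(-13, -9, length.out = 10)
panel <- tibble::tibble(dose_M = doses,
                        response = four_pl(doses, 0, 0.40, 2, 1.5e-11))
fit <- fit_4pl(panel)
glance(fit)
#> # A tibble: 1 × 5
#>       ec50  ec50_se n_points df_residual converged
#>      <dbl>    <dbl>    <int>       <int> <lgl>
#> 1 1.50e-11 2.18e-21       10           6 TRUE
```

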