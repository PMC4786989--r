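# satno2

Long-term, spatially complete records of ambient nitrogen dioxide (NO₂) —
a key marker of combustion-related air pollution — can be inferred from
satellite observations of the tropospheric NO₂ vertical column density.
`satno2` implements that inference chain as a tested R package for
exposure scientists and air-quality researchers: it splices
multi-resolution satellite column records into a self-consistent fine-grid
(0.1°) record, converts columns to ground-level concentrations with a
chemical-transport-model surface-to-column ratio, corrects for nonrandom
sampling, and computes population-weighted exposure metrics and long-term
trends. A synthetic-world module generates every input the real analysis
obtains externally — truth fields with urban hotspots and regional trends,
a surrogate transport model, three sensors with distinct footprints and
eras, gridded population, monitoring stations — with known ground truth,
so every stage is testable against a recoverable answer.

## The method in brief

For a cell \(i\) and year \(t\), the ground-level estimate is

    C_it = S_i · Ω_it · f_it

where Ω is the harmonized annual-mean tropospheric column
(10¹⁵ molec cm⁻²), S the model surface-to-column ratio (ppb per 10¹⁵),
and f the sampling-bias correction — the model-surface annual mean over
all days divided by its mean over retrieval days. Harmonization builds Ω
at the fine reference sensor's effective resolution: coarse-era years are
ratio-downscaled (`coarse × fine_ref / smoothed_ref`), late-era years are
scaled by the long-term overlap ratio of reference to target (clipped to
[0.1, 10]). Exposure is summarized as the population-weighted mean
PWM = Σ pᵢCᵢ / Σ pᵢ per region, weighted percentiles of the cumulative
population distribution, and OLS trends with 95% CIs reported in percent
per year relative to the long-term mean (significance at α ≤ 0.01,
inclusive).

## Worked example

Run the full pipeline on the default synthetic study conditions (a
20° × 10° window, four regions with configured trends +6.7, −4.7, −2.5,
−2.1 %/yr, three sensors over 1996–2012):

```r
library(satno2)
res <- run_pipeline(pipeline_config(scenario = scenario_config(seed = 42)))
print(res)
#> <pipeline_result> 1996-2012, 4 regions, seed 42
#> # A tibble: 4 × 6
#>   region_id mean_ppb rel_trend rel_ci_lo rel_ci_hi  p_value
#>       <int>    <dbl>     <dbl>     <dbl>     <dbl>    <dbl>
#> 1         1    3.43       6.35      5.49      7.21 9.81e-11
#> 2         2    0.979     -4.59     -5.06     -4.12 1.77e-12
#> 3         3    0.971     -2.52     -3.14     -1.90 3.15e- 7
#> 4         4    0.842     -2.21     -2.54     -1.88 3.29e-10
```

Each row is one region's population-weighted annual mean NO₂ (ppb),
its OLS trend relative to the long-term mean (%/yr with the 95% CI), and
the two-sided p-value. The fitted trends bracket the configured regional
rates; the fastest-growing region reads slightly below its configured
+6.7 because the OLS-relative convention applied to geometric growth
carries a small curvature offset (see the methods vignette). Follow-on
summaries chain off the result tibbles:

```r
pwm1 <- dplyr::filter(res$pwm, region_id == 1)
percent_change(pwm1$pwm_ppb[pwm1$year == 1996], pwm1$pwm_ppb[pwm1$year == 2012])
#> # A tibble: 1 × 2
#>   percent percent_rounded
#>     <dbl>           <dbl>
#> 1    172.             172
autoplot(res$pwm)   # PWM time series per region
```

The methods vignette (`vignettes/exposure-pipeline.Rmd`) documents the
model, every tunable threshold, and the design choices.

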