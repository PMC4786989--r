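---
title: "From satellite NO2 columns to population-weighted exposure trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From satellite NO2 columns to population-weighted exposure trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satno2)
```

## The problem

Ground monitors measure nitrogen dioxide where people happen to have put
instruments; most of the world's population lives nowhere near one.
Satellite spectrometers retrieve the tropospheric NO2 vertical column
density (in units of $10^{15}$ molecules cm$^{-2}$) with near-global
coverage, but three obstacles stand between a column record and an exposure
record:

1. **Columns are not concentrations.** Health-relevant exposure is the
   ground-level mixing ratio (ppb). A chemical-transport model supplies the
   spatially varying surface-to-column ratio $S_{ij}$ so that
   $C^{surf}_{ij} = S_{ij} \cdot \Omega_{ij}$, where $\Omega$ is the
   tropospheric column.
2. **Successive instruments have different footprints.** A multi-decadal
   record must splice sensors whose native pixels differ by an order of
   magnitude in area (here 3.2° × 0.4°, 0.6° × 0.3° and 0.8° × 0.4°
   rectangles on a 0.1° analysis grid). Naively concatenating them turns
   resolution changes into fake trends.
3. **Sampling is not random.** Cloud screening and snow screening remove
   data preferentially in winter, when NO2 is highest, biasing annual means
   low wherever the seasonal cycle is strong.

`satno2` implements the full chain — simulation of the raw observations,
quality control, footprint regridding with oversampling, multi-sensor
harmonization, surface conversion with sampling-bias correction,
population weighting, and ordinary-least-squares trend estimation — as
composable, individually tested functions, with a synthetic world standing
in for every external input so that each stage has a recoverable ground
truth.

## The synthetic world

Real inputs (retrieval archives, a global chemical-transport simulation,
gridded census rasters, monitoring networks) are replaced by generators
whose parameters are the study conditions:

* **Truth field.** Surface NO2 on a 0.1° grid:
  $C(x, y, t) = B(x, y)\,(1 + r_{R(x,y)}/100)^{\,y(t) - y_0}\,
  \bigl(1 + A\cos 2\pi(d(t) - d_p)/365.25\bigr)$, where $B$ is a rural
  background (0.5 ppb) plus Gaussian urban hotspots (peaks 4–8 ppb,
  e-folding scale 0.5°), $r_R$ is the per-region trend in %/yr applied
  geometrically, $A = 0.35$ is the seasonal amplitude with a mid-January
  peak $d_p = 15$ (the northern-hemisphere wintertime NO2 maximum), and
  regions are the quadrants of the window. The default window is
  20° × 10° (200 × 100 cells) with one hotspot per quadrant and trends
  +6.7, −4.7, −2.5, −2.1 %/yr — the magnitudes and signs of the strongest
  regional trends a multi-sensor satellite record resolves.
* **Surrogate model.** A 2° "model" grid carrying the block-mean surface
  field, a latitude-dependent surface-to-column ratio around
  0.5 ppb per $10^{15}$ molec cm$^{-2}$, the implied column
  ($\Omega = C/S$ exactly on the model grid), and a three-layer partial
  column profile whose boundary-layer fraction varies with latitude. The
  model resolution is square 2° rather than an anisotropic 2° × 2.5° cell:
  nothing downstream depends on the aspect ratio, and a square cell keeps
  the nesting arithmetic exact.
* **Sensors.** Three instruments with overlapping eras (1995–2003,
  2002–2011, 2007–2012), revisit periods of 3, 6 and 1 days, relative
  column noise of 30/25/25% (multiplicative Gaussian truncated at −90% so
  columns cannot flip sign by more than the signal), an averaging-kernel
  shape parameter that suppresses near-surface sensitivity, and an optional
  multiplicative calibration bias (default 1.1 on the third sensor) for the
  cross-calibration stage to remove. Footprints are grid-aligned
  rectangles; their across-track phase is an independent uniform draw per
  sensor-year keyed on the master seed, and the along-track phase is
  re-drawn daily, so long-term oversampling dithers observations across the
  footprint while any `revisit`-day run of observation days still covers
  every cell.
* **Observation days.** 73 days per year (every fifth day). This is the
  package's down-sampled stand-in for daily acquisition: it keeps the
  slowest-revisit sensor at roughly twelve sightings per cell-year before
  quality control, so the five-valid-days rule differentiates genuinely
  data-poor cell-years instead of masking entire eras.
* **Cloud and snow.** Per-footprint cloud radiance fractions are Beta
  distributed with a seasonally varying mean (0.30 ± 0.15, cloudier in the
  NO2-peak season) so that the sampling-bias correction has something real
  to correct. Poleward of 55°, snow covers the off-season with ±10-day
  yearly jitter on both edges.
* **Population.** Counts generated at 0.05°, log-normally scattered around
  the hotspot pattern, growing 1.2 %/yr, and aggregated to 0.1° by
  summation (conserving totals exactly) at five-year snapshots 1995–2015.
* **Stations.** Population-weighted site draws with a log-normal local bias
  factor; "traffic" sites get an extra ×1.5 enhancement and exist to be
  excluded by the selection rules.

What the generator deliberately does **not** emulate: real scan geometry
and orbit mechanics, retrieval spectroscopy, inter-annual meteorology,
emission seasonality beyond one harmonic, correlated retrieval errors, and
within-cell population heterogeneity. Green tests therefore demonstrate
that the machinery is self-consistent and recovers known truth under these
idealized conditions — not that any particular real-world retrieval is
unbiased.

## Quality control and regridding

Footprints with cloud radiance fraction strictly above 0.5 are rejected
(a fraction of exactly 0.5 survives). The snow filter applies the
*shortest snow-free season*: per year the snow-free interval is (last
spring snow day + 1, first autumn snow day − 1), and the final window is
the intersection over all years, applied identically to every year. The
intersection (rather than per-year windows) guarantees identical seasonal
sampling across sensor eras, which is what makes era-to-era differences
interpretable as trends; a `per_year` flag exposes the alternative.

The averaging-kernel correction replaces the retrieval's assumed profile
with the model's midmorning (10:00–12:00) profile:
$\Omega' = \Omega \cdot \sum_l x_l / \sum_l A_l x_l$ with $x$ the model
partial-column profile and $A$ the kernel. It is exact by construction in
the synthetic world (the simulator distorts with the same factor), the
identity for a unit kernel, and invariant to rescaling of $x$.

Regridding assigns every 0.1° cell the overlap-area-weighted mean of all
footprints covering it; the weight is the summed overlap area. Overlap
areas are planar rectangle intersections scaled by $\cos(\text{latitude})$
of the cell center — adequate at 0.1° and testable in closed form; cells
receiving less than 1% of their area are skipped as numerical noise.
Negative columns produced by retrieval noise are retained through daily
and annual averaging (clipping would bias low-signal means up); only final
annual surface fields are floored at zero.

## Harmonization

The record is built at the effective resolution of the fine reference
sensor (the 0.6° × 0.3° instrument, observing 2002–2011):

* **Early coarse era (1996–2003).** Each annual mean of the 3.2° × 0.4°
  sensor is multiplied by the ratio of the reference sensor's 2003–2005
  mean to a smoothed version of that mean. The textbook approximation
  of the denominator is a 3.2° × 0.4° boxcar (33 × 5 cells; windows are
  rounded up to odd cell counts and truncated at grid edges, masked cells
  excluded). The pipeline sharpens this approximation by computing the
  denominator with the coarse sensor's *own sampling operator*
  (`sensor_smear()`): the reference mean is observed with exactly the
  footprint tiling, phases and revisit schedule that produced the coarse
  record, then regridded. For a sensor whose phases dither uniformly the
  long-term operator approaches the boxcar convolved with the phase
  distribution (roughly a triangular kernel, i.e. two boxcar passes —
  `smooth_passes = 2` is the default analytic fallback); using the exact
  operator removes the residual amplitude mismatch at sharp hotspots that
  either analytic kernel leaves behind, which would otherwise masquerade
  as a spurious trend component across the era boundary.
* **Reference era (2004–2011).** Annual means pass through unchanged.
* **Late era (2012).** The third sensor's annual mean is scaled by the
  per-cell ratio of reference to target long-term means over the 2007–2011
  overlap, clipped to [0.1, 10]. A spatially uniform calibration bias
  cancels exactly.

Whole calendar years are assigned to single sensors (coarse sensor through
2003, reference through 2011, late sensor 2012); overlap years are not
blended. Ratio denominators below 5% of the area-weighted global mean of
the denominator field fall back to ratio 1 — near-zero columns carry no
usable spatial structure, only noise.

Continuity is diagnosed with per-pixel z-scores: for each pixel's annual
series, consecutive-year differences $d_t$ are computed, and the boundary
difference is scored as $z = (d_b - \bar d)/s_d$ with the sample standard
deviation over all of that pixel's differences; a constant-difference
series scores 0 by convention. The headline diagnostic is the fraction of
pixel-boundary cases with $|z| \le 1.5$.

## Surface conversion and the sampling-bias correction

Harmonized annual columns are multiplied by the model ratio, block-resampled
(nearest-neighbour) from the 2° model grid to 0.1°: fine spatial texture
comes from the satellite, not from the model. The sampling-bias correction
factor per cell-year is the ratio of the model surface averaged over *all*
observation days to its average over the days with a surviving retrieval,
computed per sensor era from that era's retrieval-day mask and applied to
the annual mean (annual application is the implemented reading; applying it
daily is algebraically identical for a multiplicative seasonal model).
Winter-deficient sampling at high latitudes therefore *raises* corrected
annual means. Cell-years with fewer than `min_days = 5` valid days are
masked, echoing the station rule of at least five satellite-coincident
observations per year; the satellite archive itself states no per-pixel
minimum, so the threshold is configurable.

## Exposure metrics and trends

The population-weighted mean over a region is
$\mathrm{PWM} = \sum_i p_i C_i / \sum_i p_i$ over unmasked cells; masked
cells drop out of both sums (weight renormalization, not zero-imputation).
Population is linearly interpolated between five-year snapshots, clamped
outside the snapshot range. Weighted percentiles use the weighted
empirical quantile with linear interpolation between adjacent cells in
cumulative-population space (no convention is canonical; this one makes
the CDF and the percentile function exact inverses). Reported percent
changes round half away from zero, and the unrounded value is always
carried alongside.

Trends are plain OLS of annual values on (centered) years, with the 95%
interval $\hat\beta \pm t_{0.975,\,n-2}\,\mathrm{SE}$ and a two-sided
t-test; significance means $p \le \alpha$ with $\alpha = 0.01$ — a p-value
exactly at the threshold counts. Relative trends divide the slope and both
CI ends by the series' long-term mean; sub-period trends divide by the
*full-period* mean so that steeper sub-periods are comparable against the
same baseline. No autocorrelation correction is applied, matching the
plain-OLS convention for this kind of record.

Station comparison excludes traffic sites, requires at least 15 years and
at least 5 satellite-coincident observations per qualifying year, averages
stations sharing a pixel, and compares *normalized* series (each divided
by its own long-term mean) — under which a multiplicative local bias
cancels exactly, which is why relative rather than absolute trends are the
meaningful point of contact between a point monitor and a 10-km area mean.

## Numerical and design choices

* Footprint overlap uses cell-center cosine latitude; sub-1% overlaps are
  dropped.
* Annual sensor means weight daily regridded values by observation area;
  pooling all of a year's footprints in one pass is algebraically
  identical and is what the fused accumulation path does (a test pins the
  equivalence to 1e-10).
* The OLS fit is `stats::lm` on centered years; the closed-form sum
  formulas live only in the test oracle.
* Exactly-fitting series get SE 0, zero CI width, and p-value 0 (or 1 when
  the slope is also 0); z-scores with zero spread score 0.
* The master seed drives every stream (granule noise and cloud draws,
  footprint phases, population scatter, station placement, snow jitter)
  through independently keyed sub-seeds, so a configuration plus a seed
  pins the entire world bit-for-bit.

One estimand subtlety is worth stating precisely: the generator applies
trends *geometrically* (exactly $r$ %/yr on the annual regional mean),
while the reporting convention is the OLS slope relative to the long-term
mean. For a noise-free geometric series over 17 years these differ by
curvature — a configured +6.7 %/yr has an OLS-relative trend of 6.36 %/yr;
the discrepancy shrinks quadratically for smaller rates (−4.7 → −4.76,
−2.5 → −2.52). Recovered trends therefore sit systematically slightly
inside the configured value for the fastest-growing region even when the
pipeline itself is unbiased. The parameter-recovery suite measures
coverage against the configured rates regardless, and the observed
coverage stays within the accepted band with this offset included.

## Problem sizes

The default study conditions used by the tests and the acceptance script
are a 200 × 100 cell window at 0.1°, 17 years, 73 observation days per
year, three sensors, 50 million people, and 50 seeded replicates for the
recovery experiment; the high-latitude sampling-bias scenario uses a
40 × 20 cell window. These sizes resolve every mechanism the pipeline
exercises (footprint contrast, seasonal sampling loss, era splicing,
population weighting) while a full replicate runs in seconds.

## Known limitations

* The downscaling transfer assumes the reference-period spatial pattern
  persists across the coarse era. Regions whose hotspots sharpen or flatten
  relative to their surroundings violate this; in the synthetic world the
  violation appears only across region boundaries within one smoothing
  window and is small, but for real records with emerging sources it is
  the leading structural error, and no test here bounds it.
* Uncertainty in the model surface-to-column ratio is not propagated; the
  surrogate ratio is treated as known, so surface-record CIs reflect
  retrieval and sampling noise only.
* Trend CIs assume independent annual residuals; the harmonization ratio
  is estimated once and shared across the coarse era, which leaves a small
  common-mode component the plain-OLS intervals do not see.
* Masked-cell renormalization changes the population composition of a
  region's PWM between years when coverage varies; with the default
  observation density this effect is at the percent level, but it grows
  quickly when sampling is sparse.
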