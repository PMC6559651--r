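---
title: "A two-life-stage habitat suitability index for intertidal rock oysters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-life-stage habitat suitability index for intertidal rock oysters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oysterHSI)
```

## The problem

Reef-forming intertidal oysters such as *Saccostrea cucullata* are
candidates for restoration along monsoon-dominated coasts, but
restoration only succeeds where the habitat supports both larval
settlement and year-round growth. A habitat suitability index (HSI)
condenses seven routinely monitored environmental variables —
water temperature, salinity, dissolved oxygen (% saturation), pH,
chlorophyll-a, particulate inorganic matter (PIM) and flow velocity —
into a single 0–1 score per site, so that candidate sites can be ranked
and mapped. `oysterHSI` implements the full chain from raw survey
records to a verified coastline suitability map.

## Model structure

### Suitability curves

Each variable is transformed to a suitability index SI ∈ [0, 1] by a
piecewise-linear curve over breakpoints (`suitability_curve()`,
`eval_suitability()`). Between breakpoints the curve interpolates
linearly; outside its span it clamps to the edge value by default
(curves plateau at their extremes), with a per-curve `zero` policy
available. Curves are *data*, not code: `load_curveset()` reads a YAML
configuration, and `default_curveset()` ships a documented approximation
whose shapes follow the species' ecology — growth salinity near zero at
0–5 ppt and maximal near 25–30 ppt, a pH optimum near 7.9–8.5, SI
increasing with oxygen saturation and chlorophyll-a, and declining with
suspended inorganic sediment. Site-specific studies should replace these
defaults with locally calibrated curves.

The growth-salinity curve can be calibrated from closed-chamber
respiration trials (`calibrate_salinity_curve()`): the oxygen
consumption rate of each trial is `RR = -V (pO2_end − pO2_start) / t`
(mL O2/h for a chamber of `V` litres over `t` hours), rates are averaged
per tested salinity, and the means are standardised so the maximum maps
to SI = 1. Replicates are averaged *before* normalisation; averaging
after would let a single noisy replicate set the scale. Trials whose
ending oxygen concentration falls below 2.1 mL O2/L (3 mg O2/L) are
flagged, since consumption becomes oxygen-limited there.

### Seasonal aggregation

The monsoon (June–September) differs sharply from the rest of the year
(October–May): salinity drops, suspended sediment spikes, chlorophyll-a
falls and flows strengthen. Records are therefore aggregated into two
seasonal mean datasets per station (`seasonal_means()`), after averaging
flood/ebb duplicate measurements within a station visit. Seasonal
contrasts can be tested per variable with `seasonal_ttest()` (Welch by
default; the pooled-variance variant is a flag — the Welch form is the
safer default when seasonal variances differ, as they typically do for
salinity and PIM).

Annual means weight the two seasonal means by season length, 4/12 and
8/12 (`annual_mean()`), not by the number of surveys (4 monsoon vs 3
non-monsoon). The distinction matters: count weighting would
over-represent the monsoon in every annual figure (e.g. a temperature
pair of 29.4/28.1 °C gives 28.8 °C count-weighted but 28.5 °C
month-weighted), and only month weighting is consistent with treating
the seasonal means as representative of their periods.

### Component indices and the HSI

Two life stages are scored per season from the SI vectors
(`si_vector()`; the salinity mean feeds both the settlement and the
growth curve):

* **Settlement** (`ci_settlement()`): the geometric mean of the
  settlement-salinity and velocity SIs per season,
  `CI_m = sqrt(SI_Ss · SI_V)`, then the *arithmetic* mean of the two
  seasonal CIs with equal weights. Settlement peaks occur in both
  seasons, and a failed monsoon spatfall can be compensated after the
  monsoon, so one bad season must not zero the stage.
* **Post-settlement** (`ci_post_settlement()`): the geometric mean of
  the six growth-stage SIs per season (1/6 power of their product);
  a zero SI for any variable zeroes the seasonal CI. Seasons combine
  *multiplicatively* because growth conditions must hold year-round.

For the cross-season combination of the post-settlement stage two
exponent conventions circulate: both seasonal CIs raised to 1/3, or
exponents proportional to season length (4/12 and 8/12). The package
defaults to the normalized season-length exponents
(`weight_mode = "normalized"`): with exponents summing to 1 the
combination is a true weighted geometric mean, bounded by the two
seasonal CIs and by [0, 1]. With the (1/3, 1/3) form, equal seasonal
CIs of c combine to c^(2/3) > c, so a mediocre year-round site is
inflated. The literal form is retained as
`weight_mode = "as_printed"` for reproducing analyses that used it; the
divergence is documented, not resolved, and both modes satisfy the same
monotonicity properties.

The overall score (`combine_hsi()`) follows the minimum-limiting rule:
if the post-settlement CI is the lowest it *is* the HSI; otherwise the
HSI is the geometric mean of the two CIs. At equality both branches
coincide, so the tie needs no convention. Categories: `suitable`
(HSI > 0.50), `less_suitable` (0.3 < HSI ≤ 0.5), `least_suitable`
(HSI ≤ 0.3).

## Coastline mapping

Station scores are interpolated over a coastline polyline by nearest
neighbour (`coastline_segments()`, `coastline_class_lengths()`). Each
polyline edge is subdivided into pieces of at most 1 km (configurable);
each piece takes the class of the station nearest its midpoint under
great-circle (haversine) distance with Earth radius 6371.0088 km, ties
broken toward the lowest station id. Segment-midpoint assignment is the
simplest discretisation of nearest-neighbour interpolation over a line;
piece lengths are exact fractions of edge lengths, so class lengths sum
to the total coastline length by construction. Lon/lat interpolation
within an edge is linear, which is adequate at sub-kilometre scales.

Class labels follow the conventional ten-bin table (`classify_hsi()`):
scores are rounded half-up to 2 decimals and binned as 0.00–0.10,
0.11–0.20, …, 0.81–0.90, 0.90–1.00 — contiguous on the rounded scale.

## Population descriptors and verification

Quadrat surveys (default 25 cm × 25 cm frames) yield three descriptors
per site (`site_summary()`): density over **all** quadrats including
zeros, shell height and condition index over measured individuals. The
condition index is `100 · dry flesh / dry shell` (%): the phrase
"shell–flesh weight ratio" is directionally ambiguous, but only
flesh-over-shell lands in the observed 4–11% range for this species, so
that direction is implemented. The site condition index is the mean of
individual ratios (the ratio-of-summed-weights alternative differs only
when sizes vary wildly within a site; individual means keep each animal
equally weighted).

Verification (`verify_hsi()`, `pearson_bootstrap()`) correlates station
HSI with site-mean descriptors — site means, not individual oysters —
and attaches 95% bounds from a paired quantile bootstrap (B = 1000
default, seed mandatory; every stochastic step in the package requires
an explicit seed). `stepwise_regression()` provides forward selection
with a removal check (enter at p < 0.05, remove at p > 0.10 — the
conventional SPSS-style pair when only the 0.05 entry level is stated),
reports the usual model summary (R, R², adjusted R², SE, F-change of
the final step) and variance inflation factors flagged at 5.
`regression_diagnostics()` tests residual normality with the
Lilliefors-corrected Kolmogorov–Smirnov test (parameters are estimated
from the residuals, so the uncorrected KS null would be wrong) and
variance homogeneity with Levene's test across fitted-value tertiles —
a grouping had to be chosen for a continuous regression, and tertiles
are the coarsest split that still detects fanning.

## The synthetic generator

No raw survey from the motivating study region is published, so
`generator_config()` + `gen_env_survey()` emulate its *structure*: 80
stations along a south→north coastline, 7 surveys (4 monsoon, 3
non-monsoon) in one calendar year, a monotone south→north salinity
decline, and a monsoon signature (salinity drop, PIM spike ~2×,
chlorophyll drop ~0.55×, velocity increase ~0.55 m/s). All generated
values are truncated to field envelopes: salinity 0.5–29.5 ppt, PIM
21–1044 mg/L, chlorophyll-a 0.8–9.6 µg/L, temperature 27–28.6 °C, pH
7.4–8.5, DO 49–91%, velocity 0.2–2.4 m/s. The generator's ground truth
(`generator_truth()`) is defined as the HSI of the noise-free seasonal
means, so estimated-vs-true comparisons isolate sampling noise.

The population generator (`gen_population()`) implements an occupancy
threshold: sites below true HSI 0.27 get zero density, above it the
expected density rises linearly to 1540 ind/m² at HSI = 1 (so a site at
HSI 0.9 sits in the 1064–1596 ind/m² band observed at the best field
sites). Quadrat counts are negative-binomial (dispersion `nb_size = 5`)
— field quadrat counts are strongly overdispersed but no distribution
is reported, so this is a documented assumption. Shell height and
condition index rise linearly in HSI (height passes 5 cm near HSI 0.5;
condition index is confined to ~4–11%). `gen_verification_sites()`
separately builds site-mean descriptors with exact target correlations
(0.87 / 0.95 / 0.98 by default) for testing the verification
statistics, since the thresholded count model and a target correlation
cannot both be imposed at once. `gen_respiration()` emulates the
salinity–respiration experiment: 8 levels (0–35 ppt in steps of 5) ×
12 replicates, 1 L chambers, ~2 h trials starting near 6 mL O2/L.

What the generator does **not** emulate: rainfall-driven hydrodynamics,
tidal or spring–neap structure, spatial autocorrelation beyond the
smooth gradient, substrate availability (the reason real surveys drop
sites), and measurement error structure of specific instruments.
Passing tests therefore demonstrate that the pipeline recovers known
structure under idealised noise — not that the model is correct for any
particular coast.

## Numerical choices and test scales

* Curve evaluation is exact linear interpolation; tests require
  agreement with a brute-force oracle to 1e-12.
* Degenerate t-tests (both seasons constant and equal) return p = 1 by
  convention rather than erroring.
* Class-length conservation is asserted to 1e-9 relative.
* The test suite uses 5–80 stations, 53–60 observations for the
  statistical recovery checks, 100–500 replicates for sampling
  distributions, and bootstrap B of 300–1000; the full suite runs in
  well under a minute.

## Known limitations

* The default curves are literature-shaped approximations, not fits;
  conclusions are only as good as the curve set supplied.
* Nearest-neighbour interpolation ignores along-shore connectivity and
  cross-channel barriers; kriging or IDW alternatives are out of scope.
* The model treats the seven variables as independent; correlated
  drivers (salinity and pH both tracking freshwater influence) are not
  modelled jointly.
* Substrate availability, a first-order control on where oysters can
  settle at all, is not a model variable.
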