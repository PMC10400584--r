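---
title: "From hourly ozone fields to county crop losses: methods and design"
author: "O3Yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hourly ozone fields to county crop losses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface ozone damages sensitive crops — soybean most of all among the major
U.S. field crops — by reducing photosynthesis and yield. When anthropogenic
NOx emissions change (for example during an economic slowdown), ozone rises
in some photochemical regimes and falls in others, and the net effect on
crop production is a spatially signed sum. O3Yield quantifies that effect:
given hourly gridded surface-ozone fields for two emissions scenarios, it
computes county-level cumulative exposures, converts them to yield losses
through a dose–response function, values them in bushels and dollars, and
differences the two scenarios regionally and domain-wide.

## The exposure index

Crop exposure is measured with AOT40, the accumulated ozone exposure over a
threshold of 40 ppb:

$$\mathrm{AOT40}\;(\mathrm{ppmV\,hr}) \;=\; \sum_{i=1}^{n} \max(C_{O_3,i} - 0.04,\; 0)$$

where \(C_{O_3,i}\) is the hourly mean concentration in ppmV and the sum
runs over the hours of a fixed growing-season window. Two conventions
questions are settled as follows:

* **Threshold boundary.** An hour with \(C = 0.04\) ppmV exactly contributes
  zero either under a "\(\ge\)" or a "\(>\)" reading of the accumulation
  condition, because the summand is the positive part \(\max(C-0.04,0)\).
  The positive-part form is used throughout.
* **Window.** The default window is May 1 – August 1 (the three-month MJJ
  growing season) accumulated over **all 24 hours** of the day. The
  conventional daylight-only AOT40 (e.g. hours 08–19) is available through
  `exposureWindow(..., hoursOfDay = 8:19)` for comparison, but is not the
  default because the 24-hour variant is what the package's scenario
  bookkeeping is calibrated against.
* **Units.** The canonical internal unit is ppmV, so the 0.04 threshold
  applies directly; ppbV appears only at I/O boundaries and is divided by
  1000 on ingestion (`convertUnits`, `readO3Cube`).
* **Missing hours.** Rejected by default. An opt-in `naAction = "skip"`
  policy drops missing hours and logs the count, but never rescales the
  total: AOT40 is a sum, not a mean, so a gap can only bias exposure low,
  and that bias should at least be visible in the log rather than silently
  patched.

## Grid-to-county aggregation

Production data live on counties; exposures live on grid cells. County
values are **area-weighted means**: the weight of cell \(j\) for county
\(c\) is the exact polygon–cell intersection area divided by the county's
grid-covered area, computed by Sutherland–Hodgman clipping of the county
ring against each cell rectangle and the shoelace formula (the package
carries its own small planar-geometry kernel; areas are exact, not
rasterised). Weights of an in-domain county sum to 1 to within 1e-9 by
construction, so county values are convex combinations of cell values.

Two orders of aggregation are defensible and they differ because AOT40 is
nonlinear (thresholded):

1. **exposure-first** (default): compute AOT40 per cell, then area-average
   the indices to the county;
2. **concentration-first**: area-average the hourly concentrations to a
   county series, then apply the index.

The default is exposure-first because the index is defined pointwise on the
underlying field and averaging concentrations first smooths peaks across a
county before thresholding, systematically lowering exposure for
heterogeneous counties. Both orders are first-class and tested
(`countyAOT40(order = )`); they coincide exactly when all hourly values
exceed the threshold (the linear regime), which is itself a test.

Counties partially outside the grid domain are renormalised over their
covered part and flagged with a `coverage_fraction < 1`, mirroring
edge-of-domain counties in continental analyses; counties fully outside get
an empty weight row, are excluded from aggregation, and are logged.

## Dose–response and valuation

Relative yield loss is linear in exposure,

$$\mathrm{RYL} = a \times \mathrm{AOT40}, \qquad a = 0.0113\ \mathrm{(ppmV\,hr)^{-1}},$$

the established soybean coefficient from exposure–yield field studies. RYL
is capped strictly below 1 (cap events warn loudly) purely as
degenerate-input protection; the cap is unreachable at realistic exposures.

How RYL combines with *observed* production is genuinely
convention-dependent, and published county assessments rarely print the
formula. Two conventions are provided:

* **compensated** (default): observed production is post-damage, so the
  lost amount is \(P \cdot \mathrm{RYL}/(1-\mathrm{RYL})\);
* **simple**: \(P \cdot \mathrm{RYL}\).

Compensated dominates simple by the factor \(1/(1-\mathrm{RYL})\) — about
1.06 at a typical 6% RYL — and the two agree to first order in RYL. The
compensated form is the default because the linear dose–response framework
this coefficient comes from defines RYL against the undamaged potential
yield. Both are selectable per run (`doseResponseParams(convention = )`).

Money is the product of bushel loss and a fixed per-bushel price (default
$9.0075, the U.S. soybean price of late August 2020). All internal
arithmetic is in full floating precision; rounding to cents is display
only. In scenario reports, bushels are summed **first** and the difference
is valued **after** summation, so the domain-wide production gain equals
`price × (total_loss_A − total_loss_B)` exactly; per-county USD columns are
informational.

Counties with withheld ("combined") production records are carried through
exposure aggregation with production `NA`, then excluded from impact tables
with a logged count; zero-production counties are retained and contribute
zero loss.

## Scenario comparison

`scenarioDifference` computes per-county deltas (perturbed minus
reference), is antisymmetric by construction, and refuses mismatched county
universes (naming the symmetric difference). Regional summaries report
per-region (min, max) ranges of exposure and loss deltas; regions with no
producing counties report exposure ranges only. The sign shares report the
percentages of producing counties with increased, improved and exactly
unchanged losses; zero deltas form their own bin (they occur exactly, not
approximately, when a county's cells are untouched by a scenario
perturbation) and the three shares sum to 100.

## The synthetic-data generator

The generator exists so every downstream stage is testable without any
atmospheric-model output or agency download. It emulates, statistically,
what a chemical-transport model and a county production table provide:

* **Fields.** `baselineMean + diurnal(hour) + noise`, with a sinusoidal
  diurnal cycle peaking at hour 15 and bottoming at hour 03 (the
  photochemical afternoon maximum), and white Gaussian noise smoothed with
  a row-normalised Gaussian kernel over `spatialCorrLength` cells. Only the
  correlation length is contractual; the kernel shape is an implementation
  detail. `noiseSd` is the pre-smoothing standard deviation.
* **Scenario deltas.** The perturbed scenario is the baseline plus a
  per-cell offset field: each configured polygon adds its signed offset to
  every cell whose centre lies inside it (overlaps sum). Outside all
  polygons the two scenarios are bit-identical, which is why untouched
  counties show deltas of exactly zero. Defaults are −1 ppbV over the
  Midwest block and +3 ppbV over the Southeast block, the signed pattern
  reported for the 2020 emissions slowdown.
* **Study conditions.** The default configuration is a 36 × 24 grid of
  12 km cells, a 92-day season (2 208 hours), mean 0.035 ppmV, diurnal
  amplitude 0.015 ppmV, noise 0.004 ppmV with a 3-cell correlation length —
  a plausible rural summer ozone climate whose 24-h MJJ AOT40 lands in the
  few-ppmV·hr range typical of the eastern U.S.
* **Counties.** A 9 × 6 rectilinear tessellation, by default *unsnapped*
  (boundaries jittered off the cell lattice) so fractional-overlap
  weighting is exercised; snapped tessellations give the trivial
  whole-cell-overlap path. Regions follow a five-rectangle layout arranged
  like the coarse CONUS regions; production is log-normal per region
  (Midwest ≫ Southeast > Northeast; Southwest/West grow none), echoing the
  real concentration of soybean production, with two withheld records.
* **Physicality.** Negative concentrations are clipped to zero with a
  logged count (essentially never triggered at the default parameters);
  clipping can be disabled for mean-shift recovery checks.

What the generator does **not** emulate: photochemical regime dependence
(NOx- vs VOC-limited sign structure arises here only through the prescribed
delta polygons), meteorological variability and synoptic persistence,
terrain and coastline effects, and the long right tail of real county
production. Passing tests therefore demonstrate the correctness of the
exposure → impact arithmetic and its bookkeeping — not that any particular
real-world scenario outcome is reproduced. With the default synthetic
conditions the +3 ppbV Southeast perturbation outweighs the −1 ppbV Midwest
one in production-weighted exposure, so the perturbed scenario shows a net
*worsening*; the sign of the net effect is a property of where production
sits relative to the deltas, not of the method.

## Numerical choices

* Polygon–cell intersection is exact clipping; a non-convex ring clipped by
  Sutherland–Hodgman can contain degenerate zero-width bridges, whose
  signed shoelace area is still the true intersection area.
* Self-intersecting county rings are rejected at construction (O(n²)
  proper-crossing check); holes and self-touching rings are unsupported.
* Weight rows renormalise over the in-domain area with a 1e-9 conservation
  tolerance, validated on every construction.
* The grid's flattened cell order is column-major over the (ny × nx) field
  matrix; one helper (`cellIndex`) owns that convention.
* Hourly cadence is validated exactly (1-hour steps); NetCDF round trips
  are bit-identical (double precision end to end).
* Reports sum county losses in table order, so totals, regional sums and
  per-county sums are identical, not merely close.

## Problem sizes

The shipped tests run the full pipeline on the default 36 × 24 × 2 208-hour
synthetic conditions (about 1 s), the AOT40 loop-oracle comparison on one
hundred 3 × 3 × 48 cubes, and the Monte-Carlo weight oracle on twenty
random polygons at 10⁵ points each — sizes chosen so the whole suite
completes in seconds while still exercising every code path, including
fractional overlaps, withheld counties and out-of-domain edges.

## Limitations

* Planar, equal-area coordinates are a documented contract: geographic
  inputs must be projected before weighting; the package never reprojects.
* The linear dose–response is a single-coefficient model; no cultivar,
  phenology-stage or water-stress modulation.
* One price, one crop, one growing season per run.
* County region membership is an input (or the synthetic layout), not a
  shipped gazetteer.
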