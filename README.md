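# O3Yield

Surface ozone is phytotoxic: season-long exposure above about 40 ppb
measurably depresses the yield of sensitive crops, soybean first among
them. When emissions change — a policy intervention, an economic slowdown —
ozone rises in some photochemical regimes and falls in others, and the net
agricultural effect is a spatially signed sum over the producing counties.

O3Yield is an R package for quantifying that effect. It takes hourly
gridded surface-ozone fields for two emissions scenarios (e.g. a
business-as-usual counterfactual "BAU" and an observed-conditions "C19"
run of an air-quality model), and produces county-level exposures, yield
losses, dollar losses, and scenario differences, for analysts working at
the air-quality/agriculture interface.

## The method

1. **Exposure.** Per grid cell, the AOT40 cumulative index over a
   growing-season window (default May 1 – Aug 1, all 24 hours):

   AOT40 (ppmV hr) = Σᵢ max(C_O₃,ᵢ − 0.04, 0),

   with hourly mean concentrations C in ppmV (ppbV inputs are converted on
   ingestion).

2. **Aggregation.** County AOT40 is the exact area-weighted mean of
   overlapped cells (polygon–cell clipping, weights summing to 1);
   a `concentration_first` option averages the hourly series before
   applying the index instead.

3. **Dose–response.** Relative yield loss RYL = a · AOT40 with a = 0.0113
   per ppmV·hr (soybean). Bushel loss uses the compensated convention
   loss = P · RYL/(1 − RYL) by default (observed production is
   post-damage), with the simple P · RYL convention selectable.

4. **Valuation and comparison.** Losses are valued at a fixed per-bushel
   price (default $9.0075); scenarios are differenced per county,
   summarised per region as (min, max) ranges, and totalled domain-wide
   with production-reduction percentages.

A synthetic-data module generates all inputs — hourly fields with an
afternoon-peaked diurnal cycle, spatially correlated noise and regionally
signed scenario deltas, plus county tessellations with region labels and
production — so the full pipeline runs and is tested without any external
data.

## Worked example

```r
library(O3Yield)
report <- runPipeline(defaultPipelineConfig(seed = 1), outputDir = NA)
report
```

```
ScenarioReport: C19 - BAU over 52 counties

Totals (price $9.0075/Bu):
 scenario total_loss_bu mean_loss_bu total_loss_usd reduction_percent
      BAU       4078109     78425.17       36733565          6.788907
      C19       4460666     85782.05       40179453          7.425758

Regional delta ranges:
    region n_counties  aot40_min  aot40_max loss_bu_min loss_bu_max
 Northeast          8 -0.1397751  0.0000000   -2200.809        0.00
   Midwest         12 -0.8284798 -0.8279707  -55542.791   -19070.53
 Southeast         14  2.1524265  2.8344174   18308.881   243788.24
 Southwest          6 -0.1538721  0.2162654          NA          NA
      West         12 -0.1819779  0.0000000          NA          NA

Production gain: -382,558 Bu = $-3,445,888
Difference in reduction: -0.637%
Counties: 41% increased loss, 44% improved, 15% unchanged
```

Reading this: under the default synthetic conditions (−1 ppbV over the
Midwest, +3 ppbV over the Southeast), exposure falls by ~0.83 ppmV·hr in
Midwest counties and rises by 2.2–2.8 ppmV·hr in the Southeast; the
production-weighted sum is a net worsening of 382,558 Bu (−$3.4 M) in the
perturbed scenario, i.e. a 0.637-percentage-point larger production
reduction. Crop-free regions (West, Southwest) report exposure ranges
only. Building-block calls print the underlying quantities directly:

```r
aot40Series(c(0.030, 0.045, 0.060, 0.041))   # 0.026 ppmV·hr
relativeYieldLoss(1)                         # 0.0113
productionLossBu(1000, 0.5)                  # 1000 Bu (compensated)
economicLossUsd(721006)                      # $6,494,461.55
```

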