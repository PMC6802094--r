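# baciveg

Before-after-control-impact (BACI) evaluation of forest vegetation
condition in protected areas, for conservation remote-sensing and
landscape-ecology work: did elevating a reserve's protection status (an
Indian Wildlife Sanctuary becoming a Tiger Reserve) benefit its vegetation,
relative to a matched control that was never elevated?

## What it computes

From dated, cloud/water-masked multiband surface-reflectance stacks, the
package derives two per-pixel condition tracks —

- greenness, EVI = 2.5 (ρ_NIR − ρ_R) / (ρ_NIR + 6 ρ_R − 7.5 ρ_B + 1)
- canopy moisture, NDII = (ρ_NIR − ρ_SWIR1) / (ρ_NIR + ρ_SWIR1)

— and compresses each year into a *brownest* / *driest* composite: the mean
of the year's least 20% of valid index values, date-stamped in fractional
years since 1984-01-01. Per pixel and per epoch (before vs. after the
impact reserve's declaration year), the trend of these annual composites is
the Sen's slope S (median of all pairwise slopes; Siegel repeated medians
optional). Pixels with fewer than 5 valid years in an epoch, and PAs with
more than 20% of their area insufficient, are dropped.

Pixels are then classified by slope signs — *improve* (S_b,after > 0 and
S_d,after > 0), *decline* (both < 0), *unclear* (mixed) for the after
epoch; *helped* / *harmed* / *unclear* analogously on the before-to-after
slope differences — and each PA is summarized as percentage area per
category. Each Tiger Reserve is matched to a Wildlife Sanctuary in the same
state with area ≥ 75 km² and mean annual rainfall within 500 mm, at the
shortest separation (next-nearest on conflicts), and matched pairs are
compared: *better* / *worse* / *ambiguous*, with differences of ≥ 15
percentage points in improvement or decline flagged *substantial*.

A synthetic scene generator plants known per-pixel piecewise-linear trends
(switching at the declaration year) and inverts the index formulas to
reflectances, so the whole chain is testable against ground truth without
satellite downloads.

## Worked example

```r
library(baciveg)

senSlope(c(0, 1, 2, 3), c(0, 2, 1, 3))
#> [1] 0.75     # median of the 6 pairwise slopes (-1, 0.5, 0.5, 1, 2, 2)

spec  <- sceneSpec(16, 16, years = c(1984, 2012), obsPerYear = 12, seed = 202)
truth <- simulateTruth(spec, 1993,
                       fractions = c(helped = 0.6, harmed = 0.25,
                                     unclear = 0.15))
sim  <- simulateStack(spec, truth)
comp <- buildComposites(computeIndices(applyQAMask(sim$stack, quiet = TRUE)))
sm   <- estimateEpochSlopes(comp, declarationYear = 1993)
sm
#> SlopeMaps: 256 pixels (16 x 16 grid), declaration 1993
#>   before epoch: 1984-1992
#>   after epoch: 1993-2012
#>   valid fraction: b_before 1.00, b_after 1.00, d_before 1.00, d_after 1.00

max(abs(slopeMatrix(sm) - trueSlopes(truth)))
#> [1] 2.130796e-17   # noiseless scenes round-trip to machine precision

composition(classifyPixels(sm, "change"), paId = "demo")
#>   pa_id   mode   helped harmed  unclear insufficient n_pixels
#> 1  demo change 60.15625     25 14.84375            0      256
```

The recovered composition is the planted 60 / 25 / 15 split, realized
exactly on the 256-pixel grid (60.16% is 154/256, the largest-remainder
allocation of 0.6). The full pipeline — PA-table simulation, matching,
per-PA scenes, classification, pair comparison, CSV + JSON-manifest
outputs — runs from one YAML config:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "baciveg"),
            "demo_out")
```

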