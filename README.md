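# braceroot

Maize stays upright partly because of brace roots — aerial nodal roots
that emerge in whorls from stem nodes and, when they enter the soil,
anchor the stalk against root lodging. `braceroot` is an R package for
quantifying that contribution from non-destructive field tests: a
portable device flexes the plant with a load cell at height *h* while a
footplate IMU records rotation, and the plant is tested repeatedly as
soil-entering whorls are sequentially excised (tests labelled `A` for
intact, then `B`, `C`, ...). It is written for field phenotypers and
plant-biomechanics researchers working with force–rotation traces from
such devices, and for anyone validating that style of pipeline against
simulated ground truth.

## The model in brief

Rotation is converted to load-point deflection by
θ = deg·π/180 and δ = h·sin θ, and the plant is treated as a tip-loaded
cantilever, so force is near-linear in deflection over the ±15° protocol.
The fitted **force–deflection slope** (N/m) is the stiffness phenotype.
Three estimators are provided: OLS on the complete trace (default), OLS on
the automatically segmented loading cycles only (≥ 10 strictly increasing
samples spanning ≥ 0.02 m), and a per-cycle RANSAC keeping the cycle with
the longest consecutive-inlier run.

Because excision leaves the stalk unchanged, anchorage is isolated by the
paired statistics

- **ratio** = FD<sub>without</sub>/FD<sub>with</sub> (lower ⇒ larger
  brace-root contribution),
- **difference** = FD<sub>with</sub> − FD<sub>without</sub> (N/m),
- per-whorl ratios (soil-closest first: `Whorl1 = D/C`, `Whorl2 = C/B`,
  `Whorl3 = B/A`), whose product telescopes to the ratio,
- a beam-length **corrected ratio** = ratio ÷ ((h − a)/h)³, which maps a
  removal that merely lengthens the cantilever (attachment height *a* down
  to the soil) to exactly 1.

The statistical layer adds ANOVA with Tukey HSD, Pearson correlation,
Tukey ladder-of-powers normalization, variance-components repeatability
R = σ²<sub>plant</sub>/(σ²<sub>plant</sub> + σ²<sub>resid</sub>) with
parametric bootstrap, and a two-predictor regression for line means. A
synthetic generator simulates whole experiments (triangle-wave protocol,
hysteresis, sensor and wind noise, plant-level random effects, whorl
factors) with ground truth attached, so every stage is testable.

## Worked example

Simulate one three-whorl plant (true intact slope 40 N/m, whorl factors
0.65/0.85/0.95), extract slopes, and compute its contribution:

```r
library(braceroot)

series <- simulate_removal_series(
  plant_truth(40, whorl_factors = c(0.65, 0.85, 0.95),
              attachment_height_m = 0.025),
  protocol_config(), seed = 11
)
slopes <- vapply(series$traces,
                 function(tr) fit_slope_full(tr)$slope_N_per_m, numeric(1))
round(slopes, 2)
#>     A     B     C     D
#> 37.12 34.95 30.06 19.42

contribution_result(slopes, load_height_m = 0.64, attachment_height_m = 0.025)
#> <brace-root contribution> ratio 0.5231, difference 17.7 N/m
#>   per-whorl: Whorl1=0.6459, Whorl2=0.8601, Whorl3=0.9417
#>   beam-length corrected ratio 0.5896
```

The slope falls at every excision; the per-whorl ratios recover the
generating factors (soil-closest whorl contributes most), the overall
ratio 0.52 means the plant keeps about half its stiffness without brace
roots, and the corrected ratio stays well below 1 — the loss is real
anchorage, not beam geometry. The full pipeline over a 23-plant removal
experiment:

```r
ds  <- simulate_experiment(design_removal_cml258(), seed = 3)
sl  <- pipeline_extract(ds, method = "full")
co  <- pipeline_contribution(sl, ds$metadata)
pipeline_stats(co, sl, seed = 3)
#> == Brace-root anchorage report ==
#> Removal effect (one-way ANOVA across test labels): F = 19.2, p = 2.49e-09
#> ...
#> Ratio vs whorls in soil: r = -0.788, p = 8.15e-06
#> Per-whorl ratio means: whorl1 = 0.648, whorl2 = 0.854, whorl3 = 0.945
```

Field data enter the same way through `read_trace_csv()` /
`read_metadata_csv()` and `assemble_series()`; see the vignette in
`vignettes/anchorage-pipeline.Rmd` for the model, parameter and design
discussion.

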