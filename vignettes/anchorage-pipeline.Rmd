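---
title: "From force-rotation traces to brace-root anchorage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force-rotation traces to brace-root anchorage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braceroot)
```

## The measurement and its model

A portable lodging-resistance device flexes a standing maize plant with a
load cell mounted at height $h$ on a vertical post while an IMU on the
hinged footplate records the rotation angle. One test produces an ordered
force-rotation trace. The pipeline converts rotation to the horizontal
deflection of the load point,

$$\theta = \mathrm{deg} \times \pi/180, \qquad \delta = h \sin\theta,$$

and treats the plant as a tip-loaded cantilever with a rigid base: over the
small protocol angles (three cycles to roughly 15 degrees) force is close
to linear in deflection, and the fitted force-deflection (FD) slope, in
N/m, is the working stiffness phenotype. The slope mixes stalk properties
with the anchorage provided by the root system; because excising brace
roots leaves the stalk untouched, changes in the slope across a
whorl-removal series isolate the anchorage contribution of the excised
whorls. Full machine-precision $\pi$ is used in the conversion; a truncated
value such as 3.1415 would perturb slopes by under $3\times10^{-5}$
relative, which is far below sensor noise.

## Cycle segmentation and the three slope estimators

Field traces contain three loading/unloading cycles plus operator and wind
noise. `parse_loading_cycles()` marks a loading cycle as a maximal run of
*strictly* increasing deflection of at least `min_run = 10` samples whose
span is at least `min_span_m = 0.02` m. Two of these choices are genuinely
open and are resolved as follows:

* *Strictness.* "Monotonically increasing" is read as strictly increasing;
  an exact tie breaks the run. With continuous-valued sensors ties are
  measure-zero, and strictness gives a crisp, testable rule.
* *Cycle extent.* Only the start criterion is forced by the run length; the
  cycle is extended to the end of the same maximal increasing run, the
  simplest rule that keeps exactly the loading samples.

Three estimators of the FD slope are provided:

1. **full** — OLS of force on deflection over *every* sample, loading and
   unloading. This is the default working method: it needs no cycle
   identification and therefore cannot be biased by a manual or failed
   definition of the loading data.
2. **loading** — OLS pooled over the samples inside accepted cycles only.
3. **ransac** — a random-sample-consensus line per cycle; the reported
   slope comes from the cycle whose consensus set has the longest run of
   *consecutive-index* inliers (ties to the earliest cycle). The
   consecutive-run reading is chosen deliberately: it penalises cycles
   disturbed mid-way (a wind burst) even when their total inlier count is
   high.

All OLS fits include an intercept: load cells carry pre-contact offsets in
the field, and the slope is the quantity of interest. RANSAC defaults are
200 two-point hypotheses per cycle and an inlier threshold of 1.5 times
the median absolute residual of a preliminary full fit, floored at
$10^{-8}$ N so noise-free data are never rejected; the seed is an explicit
argument, making the stochastic method bit-reproducible.

When no cycle passes both filters — which a sustained wind burst can cause
— the loading and RANSAC methods raise a no-cycle condition and the
pipeline falls back to the full fit, flagged in the output, rather than
dropping the plant.

## Contribution calculus

For a plant whose soil-entering whorls are excised top-down between tests
labelled `A` (intact) through the last label:

* ratio $= FD_\mathrm{without}/FD_\mathrm{with}$ (last/A) — lower means a
  larger brace-root contribution; dimensionless and insensitive to the
  plant's baseline stalk stiffness,
* difference $= FD_\mathrm{with} - FD_\mathrm{without}$ (A − last) in N/m,
* per-whorl ratios numbered from the soil up (three whorls:
  `Whorl1 = D/C`, `Whorl2 = C/B`, `Whorl3 = B/A`), whose product
  telescopes exactly to the overall ratio.

**Beam-length correction.** Brace roots attach at height $a$ above the
soil (measured range 0.015–0.032 m), so their removal also lengthens the
effective cantilever from $h-a$ to $h$. Under the tip-loaded cantilever
law (slope $\propto 1/L^3$), a removal that changed *only* the beam length
would produce a raw ratio of $((h-a)/h)^3$. The corrected ratio divides
this factor out, so the pure-geometry null maps to exactly 1 — the only
internally checkable anchor for the correction, and the reason the
divisive form is the default. The multiplicative reading remains available
via `direction = "multiply"` for comparison; neither direction is claimed
to be uniquely canonical, and the package asserts only the null-to-1 and
$a = 0$ identities. Plants without an attachment-height measurement return
`NA` rather than a silently uncorrected value.

## Statistical layer

The analysis surface mirrors common field-biomechanics practice: Pearson
correlation (`cor.test`), one-way and additive two-way ANOVA (`aov`),
Tukey HSD (`TukeyHSD`), and a two-predictor OLS regression for line means
(flowering time and plant height as correlated predictors with opposing
effects). Two components are implemented in-package:

* **Repeatability** — the intraclass correlation
  $R = \sigma^2_\mathrm{plant}/(\sigma^2_\mathrm{plant} +
  \sigma^2_\mathrm{residual})$ from one-way ANOVA variance components
  (Searle's estimator, valid for unbalanced groups, negative component
  truncated at 0). The SE and central CI come from a parametric bootstrap
  (default 1,000 draws from the fitted Gaussian components); the p-value
  against $R = 0$ from a permutation test of group labels, chosen over a
  likelihood-ratio test because it is assumption-light and exactly
  reproducible under a seed. The Gaussian *agreement* form is computed; on
  balanced data the estimator coincides with REML (checked against lme4 in
  the test suite).
* **Tukey's ladder of powers** — a grid search over
  $\lambda \in [-2, 2]$ in steps of 0.025, transforming by $x^\lambda$
  ($\lambda>0$), $\log x$ ($\lambda=0$) or $-(x^\lambda)$ ($\lambda<0$) and
  maximising the Shapiro–Wilk $W$. Since the grid contains 1, the chosen
  transform never fits worse than the raw data. The published workflow this
  follows states the normality gate as "transform when $p \ge .05$", which
  would transform already-normal data; the package defaults to the
  evidently intended gate (transform when normality is *rejected*) and
  exposes `gate = "p_ge"` to reproduce the literal wording.

## What the synthetic generator emulates

`simulate_trace()` produces a triangle-wave rotation protocol (default
three cycles, 50 samples per leg, 15-degree peak, load at 0.64 m) with
force $k\,\delta$ on loading legs, $\gamma k\,\delta$ on unloading legs
($\gamma \in (0,1]$ the hysteresis factor), iid Gaussian sensor noise
(default SD 0.2 N, a plausible load-cell plus contact noise floor — the
device literature reports no noise magnitudes, so this is an assumption),
and optional wind bursts: AR(1)-correlated noise added to both force and
rotation over a window, the mechanism that breaks monotone runs and
exercises the fallback policy.

Population structure is layered on top by `simulate_experiment()`:

* base slopes $\sim N(40, 8^2)$ N/m across plants — a wide but realistic
  spread for senescing inbred maize;
* per-whorl anchorage factors, default $(f_1, f_2, f_3) = (0.65, 0.85,
  0.95)$ soil-closest first, multiplicative on the slope so that the
  extracted per-whorl ratios are *exactly* the generator parameters; the
  defaults reproduce the qualitative ordering in which the whorl closest
  to the soil contributes most;
* a per-plant hysteresis factor drawn once from $U(0.70, 0.95)$ and held
  constant across that plant's tests. Within a plant the full-fit bias
  from hysteresis cancels in every ratio (the same argument that justifies
  using the full fit on real data); across plants it decorrelates the
  methods mildly, which is what makes the three-method comparison
  non-trivial;
* per-test repositioning error (within-plant SD, default 3 N/m) applied
  between repeat tests only — the working assumption is that the footplate
  stays aligned while whorls are sequentially excised, so removal series
  are limited by sensor noise, while repeat-test designs carry the full
  within/between variance structure. With between-plant SD 8 and within
  SD 3 the default between-plant variance share is $64/73 \approx 0.877$,
  matching the high repeatability reported for this class of measurement;
* optional time-of-day multipliers on the slope (morning-high turgor
  pattern) and two plot replicates of near-equal size
  (`design_removal_cml258()` bundles the 23-plant, 12 + 11 removal
  layout).

For the line-mean regression, `simulate_line_means()` draws correlated
predictors (DTS/PH, $r = 0.8$) with true effects $+0.44$ and $-0.07$. The
predictor spreads and residual SD (5.4 d, 20 cm, 1.86 N/m) were set
jointly so that at 26 lines the model sits near $R^2 = 0.4$ *and* the
height effect is detectable at roughly $t \approx 2.3$ — matching both
summary statistics rather than only one.

**What is not emulated:** soil constitutive behaviour, root depth and
guy-wire tension mechanics, viscoelastic or rate-dependent stalk response,
operator-specific device handling, and non-Gaussian sensor pathologies.
Passing recovery tests therefore demonstrates the *pipeline's* correctness
on data satisfying the linear-elastic cantilever model with multiplicative
whorl effects — not that real plants obey that model.

## Validation sizes and numerical choices

The test suite validates, among others: noise-free closed-loop recovery of
all three methods to 0.1% over slopes of 10–100 N/m; the telescoping
identity to $10^{-12}$ over 1,000 randomized series; the beam-correction
null to $10^{-9}$; whorl-factor recovery (MAE $\le 0.05$, observed about
0.008) over 200 simulated plants; repeatability recovery at the 23-plant
$\times$ 3-repeat design (mean $\hat R$ over 200 replicate datasets within
0.05 of the generating share 0.876, null-design CIs covering 0); ANOVA and
Tukey type-I error within $[0.04, 0.06]$ over 2,000 null simulations at
$k = 3$, $n = 20$; and pairwise method correlations of at least 0.76 on a
noisy 100-plant population. These problem sizes were chosen to keep Monte
Carlo error comfortably below each tolerance while the whole suite runs in
a couple of minutes on a single core.

Degenerate inputs are signalled, not guessed at: zero deflection variance,
empty cycle lists, all-identical ANOVA groups, collinear regression
designs, non-positive values offered to power transforms, and missing
attachment heights all raise classed conditions (or return `NA` where the
contract says "skip"), and the pipeline reports per-plant problems instead
of dropping rows silently.

## Known limitations

* The cycle parser's strictness and end-of-run rule are conventions; a
  device with quantised angle output could produce spurious ties and would
  need a weak-inequality variant.
* The beam-length correction direction cannot be fixed from first
  principles here; only the null behaviour is asserted.
* The repeatability estimator is the one-way Gaussian agreement form; no
  link-scale or multi-factor REML machinery is provided.
* Ratios assume positive slopes; a plant whose post-excision fit is
  non-positive (severe wind contamination) is reported as a problem rather
  than analysed.
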