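---
title: "Methods: response surfaces, particle swarms, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response surfaces, particle swarms, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmpso)
```

## The problem

A two-ingredient food formulation — here, the amount of bulgur (X1, g) and
water (X2, mL) in a pilaf — is scored by a sensory panel on the 9-point
hedonic scale for taste, color, smell and general acceptance.  The analysis
pipeline this package implements is the standard one for such studies:

1. lay the trials out as a **central composite design** (CCD) over the two
   factors;
2. fit a **full second-order polynomial** to each response by ordinary
   least squares,
   $$y = b_0 + b_1 X_1 + b_2 X_2 + b_{11} X_1^2 + b_{22} X_2^2 + b_{12} X_1 X_2;$$
3. **maximise** each fitted surface over the feasible rectangle, both with a
   stochastic optimiser (a particle swarm) and with deterministic references
   (the analytic stationary point and an exhaustive grid search), and check
   that they agree.

The package ships the twelve published second-order sensory models for
three heritage bulgur varieties (Siyez, Firik, Karakilçik × four responses)
as a verbatim registry, the published 13-run design and per-run panel
means, and a synthetic hedonic-panel generator so every stage can be tested
end to end without the original raw panel data.

## The design and the coded-to-natural map

The design is a five-level, two-factor CCD: 4 factorial points at coded
±1, 4 axial points at ±α, and 5 replicated centre points — 13 runs.  α is
fixed at **1.41**, the two-decimal value the source design uses, not √2.

A subtlety worth stating: the published axial naturals (130/150 g,
350/450 mL) are *not* the linear images of ±1.41 (those would be
132.95/147.05 and 364.75/435.25).  `factor_spec()` therefore carries an
explicit coded→natural level map that overrides linear scaling at design
levels, with linear interpolation only as the fallback for off-design
levels.  This reproduces the published design table exactly and makes
coded↔natural round trips exact on all five levels.

```{r}
d <- pilaf_design()
head(d$design, 3)
```

Run order is the published fixed listing by default; a permutation seed is
available for simulation studies but never used in validation.

## Fitting and ANOVA

`fit_quadratic()` fits in **natural units**, because the published
equations are printed in natural units and direct comparability with the
registry is the point.  The 13 rows enter as printed — the five identical
centre replicates deliberately weight the fit at the centre, as the
original analysis did.

`anova_decompose()` reports adjusted (partial, drop-one) sums of squares
per monomial, mirroring the output of the design-of-experiments software
this kind of study is analysed with, and splits the residual into lack of
fit and pure error using the replicate groups.  Published tables print
*identical* means for all centre replicates, so their pure-error SS is
exactly zero; in that case the lack-of-fit F is **flagged undefined**
(`lack_of_fit_defined = FALSE`) rather than fabricated from a zero
denominator.

### Rounding drift: why the refit and the printed predicted column differ

Refitting the published Karakilçik taste means reproduces the published
R² (99.93%) and the printed coefficients at their rounding precision.  But
the published per-run "predicted" column is *not* the refit evaluated at
the design points: it is the **printed, rounded equation** evaluated there.
The distinction matters numerically.  Rounding the X2² coefficient from
−3.207×10⁻⁵ to −3.3×10⁻⁵ alone shifts predictions by ≈0.15 at X2 = 400, so
the full-precision refit and the printed column disagree by up to ≈0.09
even though they describe the same fit.  The package therefore exposes both
columns in `run_refit()` (`refit_predicted` and `registry_predicted`), and
the validation tests compare the printed column against the registry
surface, which reproduces it to print precision.

A related transcription issue: the published narrative R² list for Siyez
repeats 99.10% for both smell and general acceptance; refitting the printed
general-acceptance means gives 96.79%.  The tests assert the eleven values
that verify and document this exclusion.

## The registry and its anomalies

`printed_model()` stores all twelve equations verbatim, including two
anomalies, because the published optimum table is reproducible **only**
from the as-printed forms:

* the Siyez general-acceptance equation prints two X1·X2 monomials
  (−0.004444 and +0.002299) and no X1² term.  Evaluation sums duplicates,
  and the published best score (−137.441 at 135 g, 375 mL) falls out
  exactly.  A `form = "corrected"` variant re-reads the first cross term as
  X1², flagged clearly, and is never used for validation;
* the Siyez taste equation's constant/linear terms put much of the surface
  far off the 9-point scale (its published optimum scores 125.101).  It is
  kept as printed; the package treats it as an objective function, not a
  hedonic prediction.

## Particle swarm optimiser

The optimiser is the canonical global-best PSO,
$$v \leftarrow w v + c_1 r_1 (p_i - x) + c_2 r_2 (p_g - x), \qquad
  x \leftarrow x + v,$$
with the published calibration as defaults: swarm 10, 40 iterations,
c₁ = c₂ = 0.10, inertia w decaying **linearly from 0.90 in the first
iteration to 0.30 in the last**, 30 independent runs per objective, and
maximisation native (no sign flip), so the negative Siyez-acceptance
optimum is meaningful as a maximum.

Choices the source leaves open, decided once here:

* **Search bounds.**  Not stated in the source.  Every published optimum —
  including the exact boundary coordinates 135/150/375/425 — is consistent
  with X1 ∈ [135, 150], X2 ∈ [375, 425], which is the default
  "reproduction" rectangle; the full experimental region
  [130, 150] × [350, 450] is one flag away.  Under the wider region the
  Siyez-acceptance corner moves to (130, 375) and scores ≈ −135.19, which
  is how the discrepancy is documented.
* **r₁, r₂ granularity.**  One uniform draw each per particle per
  iteration, shared across the two dimensions, matching the scalar form of
  the update equations.
* **Boundary handling.**  Positions are clamped component-wise; velocity is
  left unchanged.  Clamping is what makes corner optima land *exactly* on
  the bounds, as the published optimum table's 425.000-style coordinates
  indicate; it is also why best-of-30 scores at corner optima match the
  grid oracle to machine precision.
* **Initial velocities.**  Uniform in ±10% of each dimension's range
  (configurable); the source is silent.
* **Velocity clamping.**  Off by default (position clamp only); available
  as a fraction of range.
* **Per-run seeds.**  Run *k* of a multi-run uses `seed + k − 1`, making
  the 30-run best/mean/SD statistics and their serialization byte-exact
  reproducible from the master seed.

The independent check on the swarm is `bounded_optimum()`: an exhaustive
coarse grid (default 0.5 natural units) with one refinement pass at 0.001
around the best cell.  For every registry surface the best-of-30 swarm
score is required to sit within 0.02 of this oracle; for interior optima
the oracle itself agrees with the analytic `stationary_point()` to grid
resolution.

## Synthetic hedonic panels

`simulate_panel()` generates the world the pipeline assumes: a known
quadratic truth over the design, scored by `n_panelists` independent
assessors with i.i.d. Gaussian noise, summarised per run as mean ± SD in
the published table layout.  Defaults state that world once:

* `n_panelists = 50` — the study's panel size;
* `noise_sd = 1.0` hedonic units — a typical between-assessor spread for a
  semi-trained panel; it puts the run-mean standard error at
  1/√50 ≈ 0.14, the same order as the published per-run SDs (0.03–1.27).
  The source reports no per-panelist variance, so this is a simulation
  parameter, not an estimate of the study's panel;
* scores are **clipped** (not rounded) to [1, 9] by default, since
  published tables report continuous means; whole-point ballots are a flag.
  Clipping that moves more than half of all scores triggers a
  truth/scale-mismatch warning;
* panelist random effects are deliberately absent (the source models
  none); the generator also does not emulate session effects, presentation
  order, or panelist training.

Consequently a green recovery test establishes that the *estimator* is
correct under the stated noise model — not that real panel data meet that
model.  `recovery_experiment()` runs simulate → fit → optimise replicates
and reports per-coefficient bias/RMSE and the argmax recovery error; tests
check exact recovery at σ = 0, monotone improvement as σ shrinks, and the
n^(−1/2) scaling in panel size (run at a scaled-down replicate count to
stay inside the test-time budget).

## Numerical choices

* Stationary points: the 2×2 gradient system is solved directly; the
  system is declared degenerate when |det H| ≤ 10⁻¹² on the scale of the
  coefficients, and classification uses the sign pattern of det H and the
  leading diagonal.
* Percent difference uses the experimental-value denominator by default;
  eleven of the twelve published validation cells match that convention.
  The one cell consistent with a predicted-value denominator (Siyez taste,
  3.22) is covered by the `denominator = "predicted"` option.
* Hue angle uses the quadrant-correct two-argument arctangent mapped to
  [0°, 360°); a bare tan⁻¹(b/a) would silently reflect negative-a colors.
  The ΔE reference color is always caller-supplied.
* All validation tolerances in the test-suite are stated per criterion
  (±0.005 for exact registry arithmetic, 0.02 for PSO-vs-oracle, 0.5
  percentage points on R²) and are never widened at run time.

## Known limitations

* Only the two-factor CCD path is exercised; `build_ccd()` rejects other
  factor counts rather than silently generalising.
* The grid oracle is exhaustive and therefore only suitable for cheap
  objectives in low dimension — which is exactly its role here.
* The swarm implements the global-best topology only; no constriction
  factor, no islands.
* Published color values in the source's abstract disagree with its
  results section; the package tests against the results-section values,
  which are internally consistent with the printed chroma and hue.
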