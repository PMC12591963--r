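# rsmpso

Response surface methodology (RSM) coupled with particle swarm
optimisation (PSO) for two-factor sensory formulation studies — built
around the published optimisation of three heritage bulgur-pilaf
formulations (Siyez, Firik, Karakilçik) over bulgur amount (X1, g) and
water amount (X2, mL).

**Who it is for:** food scientists and sensory analysts running
designed-experiment formulation studies who want the full computational
chain — design construction, quadratic model fitting with ANOVA, surface
optimisation, and stochastic-vs-deterministic cross-validation — as
tested, scriptable code rather than point-and-click software output.

## What it computes

* **Central composite designs** (`build_ccd`, `pilaf_design`) with explicit
  coded↔natural level maps (α = 1.41, five levels per factor, replicated
  centre), exact to the published 13-run design.
* **Second-order response surfaces**
  `y = b0 + b1·X1 + b2·X2 + b11·X1² + b22·X2² + b12·X1·X2`
  fitted by OLS in natural units (`fit_quadratic`), with adjusted-SS ANOVA
  and a lack-of-fit / pure-error split (`anova_decompose`).
* **A verbatim registry** of the twelve published sensory polynomials
  (`printed_model`), anomalies included, plus the published per-run panel
  means (`sensory_table`) and optimum validation rows (`sensory_optimum`).
* **Three optimisers that must agree**: the analytic stationary point
  (`stationary_point`), an exhaustive grid oracle (`bounded_optimum`), and
  a global-best particle swarm with linear inertia decay 0.90 → 0.30,
  swarm 10, 40 iterations, c1 = c2 = 0.10, 30 independent runs
  (`pso_maximize`, `multi_run`).
* **Quality metrics**: DPPH percent inhibition `(A0 − A1)/A0 × 100`;
  CIELAB chroma `C = √(a² + b²)`, quadrant-correct hue angle
  `h = atan2(b, a)` in degrees, and total color difference
  `ΔE = √(ΔL² + Δa² + Δb²)`.
* **A synthetic hedonic-panel generator** (`simulate_panel`,
  `recovery_experiment`) for end-to-end parameter-recovery testing.

## Worked example

Validate the four Karakilçik surfaces — 30 PSO runs each against the grid
oracle over the reproduction rectangle X1 ∈ [135, 150], X2 ∈ [375, 425]:

```r
library(rsmpso)
run_validation(workflow_config(varieties = "karakilcik", seed = 1))
#> <validation_report> 4 surface(s), all PASS
#>     variety           response      x1  x2    best    mean        sd ...
#>  karakilcik              taste 141.990 425 6.91773 6.91343 0.0119828
#>  karakilcik              color 143.109 425 7.45047 7.44705 0.0145802
#>  karakilcik              smell 150.000 425 8.08312 7.99404 0.1868525
#>  karakilcik general_acceptance 142.498 425 7.53853 7.53330 0.0213511
```

Each row is one sensory objective: the swarm's best formulation (`x1` g
bulgur, `x2` mL water), its best/mean/SD over 30 runs, and the deviation
from the exhaustive grid search (here ≤ 1e-9 — corner and interior optima
alike match the published optimum table: taste 6.918 at (141.990, 425),
smell 8.083 at (150, 425), ...).

Refit the published Karakilçik taste means and compare with the printed
model:

```r
run_refit(sensory_table("karakilcik", "taste"), "karakilcik", "taste")
#> <refit_report> R2 = 99.92%
#>  run  x1  x2 mean refit_predicted registry_predicted
#>    1 140 400 6.53           6.529              6.605
#>    2 150 400 5.68           5.691              5.769
#>  ...
```

`registry_predicted` (the printed equation evaluated at the design points)
reproduces the published predicted column exactly; `refit_predicted` (the
full-precision OLS refit) differs from it by up to ≈ 0.08 — drift injected
purely by the published coefficient rounding.  See the methods vignette
(`vignettes/rsm-pso-methods.Rmd`) for why, and for every other numerical
convention.

A command-line wrapper is installed at `inst/cli/rsmpso`
(subcommands `design`, `simulate`, `fit`, `optimize`, `validate`).

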