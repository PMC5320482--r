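---
title: "Chemometric optimization and validation of multi-residue methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric optimization and validation of multi-residue methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemvalid)
```

## Scope and model

`chemvalid` implements the statistical spine of a multi-residue method
study: screening many candidate extraction/cleanup factors, optimizing
the few that matter, validating the resulting assay, and budgeting its
measurement uncertainty. The package is driven from R — the exported
functions plus `build_report()` are the interface, and this vignette is
the methods reference.

The running example is a QuEChERS-style LC–MS/MS assay for five
post-harvest pesticides. Five factors are screened (toluene % of the
acetonitrile extraction solvent, 0–100; HCl %, 0–0.5; PSA, 0–50 mg;
C18, 0–20 mg; GCB, 0–20 mg), all treated as ordinary continuous
factors coded linearly onto $[-1, +1]$ (the solvent composition is one
factor, not a mixture design). Star points may code beyond $\pm 1$;
natural sorbent masses are clamped at physical zero with a warning,
because 0 mg is a legitimate boundary setting.

## Screening: Plackett–Burman with pure-error t-tests

The 12-run design is built from the standard cyclic generator row
`+ + − + + + − − − + −` plus a final all-minus row; unused columns are
dropped. This canonical construction is fully reproducible and gives
exact 6/6 balance and pairwise orthogonality for any number of factors
from 2 to 11. Three all-zero center points are appended by default.

The main effect of factor $j$ is $\bar y_{+1} - \bar y_{-1}$ over the
twelve two-level runs. The error term is **pure error from the center
replicates only** ($s_{pe}$, $df = n_c - 1 = 2$ by default), not the
regression residual: center points are genuine replicates, and with a
saturated screening design the residual would be contaminated by real
effects. Each effect is tested two-sided at $\alpha = 0.05$ with
$SE = s_{pe}\sqrt{1/n_+ + 1/n_-}$; no multiplicity correction is
applied, matching the per-factor 95 % line of a standardized Pareto
chart. With only two error degrees of freedom the critical value is
large (4.303), so the test is deliberately conservative; a degenerate
$s_{pe} = 0$ flags the whole table rather than fabricating p-values.
The six idle generator columns are retained internally but excluded
from reporting.

## Optimization: CCD, quadratic fits, lack of fit

The central composite design joins $2^f$ factorial points, $2f$ axial
points at $\pm\alpha$ and replicated center points. Defaults are the
rotatable $\alpha = (2^f)^{1/4}$ (1.682 for three factors) and six
center points — the classic 20-run design for $f = 3$. Face-centered
and custom $\alpha$ are available. `n_center = 0` is an error because
the lack-of-fit test needs pure error.

Fitting is always done in coded units (conditioning, comparability);
the full $1 + 2f + f(f-1)/2$-term second-order basis is retained with
no backward elimination, so $R^2$ refers to the full model. Degenerate
zero-variance responses get $R^2 = 0$ with a warning. The residual sum
of squares is partitioned into pure error (pooled within replicated
design points) and lack of fit; $F_{lof}$ non-significance (p > 0.05)
supports the quadratic approximation. Tests verify the fit against a
brute-force normal-equations solve, check residual orthogonality to
$10^{-8}$, and confirm by Monte-Carlo that lack-of-fit p-values are
calibrated under a quadratic truth and powerful (> 80 % rejection)
against a strong cubic misspecification.

## Desirability

Only the larger-is-better Derringer branch is implemented (recoveries
are to be maximized): $d = 0$ below $L$, $((y-L)/(T-L))^s$ between,
$1$ above $T$, combined as $D = (\prod d_i)^{1/n}$. Defaults are
$s = 1$ and **auto-range anchors**: $L$ and $T$ are set per response to
the min and max of that model's predictions over the optimization
region, so the best reachable point of the region attains $d_i = 1$.
This mirrors common DOE software, which reports desirability 1.0 at
whatever recovery the region can best achieve (even if that is 90 %),
and makes $D$ comparable across analytes with different plateaus.
Fixed anchors are available for absolute targets.

The optimizer evaluates $D$ on a dense grid (default $21^f$) over the
coded cube $[-1, +1]^f$, breaks ties toward the smallest coded norm
(then lowest factor index), and refines the best point with L-BFGS-B
inside the bounds. Tests compare it with an exhaustive $101^3$ grid
oracle to within $10^{-3}$ in $D$. The region can be widened to the
star radius, but the cube default keeps optima inside settings that
were actually spanned by factorial points; a boundary optimum such as
0 mg GCB is representable either way.

## Validation rules

* Calibration is unweighted OLS (weighting behind a config flag), at
  least five levels.
* $ME(\%) = (slope_{matrix}/slope_{solvent} - 1)\cdot 100$. Band
  conventions are literal: $|ME| \le 20$ is *none* (inclusive),
  $|ME| > 50$ strict is *strong*, otherwise *medium*. Display rounding
  is half-away-from-zero to integers; full precision is kept
  internally.
* Two dilution-improvement summaries are provided because the field
  quotes both without defining them precisely: the percentage of
  analytes whose $|ME|$ decreased after 10-fold dilution (default) and
  the percentage of strong matrix effects resolved to non-strong.
  Neither is privileged.
* LOQ is **validation-based**: the lowest spike level with mean
  recovery in $[70, 120]$ % (inclusive) and all RSDs strictly below
  20 % — not a signal-to-noise construct.
* Inter-day precision assumes 3 days × 5 replicates = 15 by default;
  counts are configurable and deviations are reported as errors naming
  the deficit.
* Survey records with censored (`NA`) concentrations never count as
  positive; a sample is positive when any analyte is quantified at or
  above its LOQ. Ratios are displayed as integer percent.

## Uncertainty budget

Components are kept as dimensionless relative fractions and combined
as $U_c = \sqrt{\sum U_i^2}$, $U_{exp} = 100\,k\,U_c$ with $k = 2$.
$U_1$ (standards preparation) propagates purity, weighing and
volumetric tolerances, rectangular ($/\sqrt3$) by default. $U_2$ uses
the standard calibration-prediction formula
$s_{x_0} = (s_y/|b_1|)\sqrt{1/m + 1/n + (x_0-\bar x)^2/S_{xx}}$,
validated in tests against a parametric-bootstrap oracle. $U_3$ is the
assay RSD/100 (per determination by default), $U_4$ the relative
standard error of the mean recovery $(s_R/\sqrt n)/\bar R$. Reports
round $U_c$ to 4 decimals and $U_{exp}$ to 1 decimal,
half-away-from-zero. Note that recombining *rounded* components can
disagree in the last digit with a budget carried at full precision;
the bundled dataset exhibits this for two of its five analytes, and
the affected cells are treated as display artifacts rather than
assertion targets.

## The synthetic-data generator

`make_default_truth()` fixes the latent state of a plausible method
study; simulators add only seeded noise, so the truth never changes
with the seed used for a particular simulation.

* **Recovery surfaces** (coded units, recovery %): intercept ≈ 92,
  toluene and HCl linear terms ≈ +2 and +3 with concave curvature
  (−8, −6), a strong negative GCB slope (−5) for three analytes and a
  weak positive one (+0.8) for the other two (planar-analyte
  adsorption asymmetry), zero GCB curvature so the GCB optimum sits on
  the low boundary, and a small (±0.3) seeded jitter differentiating
  analytes. Responses are clipped to [0, 110] % so desirability
  anchors stay meaningful.
* **Response noise** SD is 1.0 recovery-% — a realistic replicate SD
  for LC–MS/MS recovery determinations; screening power tests instead
  plant effect-to-noise ≥ 6 explicitly.
* **Calibration**: signal = slope × ME-factor × concentration ×
  (1 + ε), ε ∼ N(0, CV²) with CV = 2 %; the per-matrix ME factors
  mirror the bundled slope-ratio table, and 10-fold dilution removes
  60 % of the deviation from 1 (`dilution_shrink = 0.6`), so
  $|ME_{D10}| < |ME_{ND}|$ by construction.
* **Recovery replicates**: mean 90 % with between-day SD 3 % and
  within-day SD 4 % — a one-way variance-components layout.
* **Surveys**: 85 samples across eight commodities (20/10/10/20/5/5/
  10/5), prevalence 0.12, log-normal concentrations (meanlog 2.0,
  sdlog 0.6 in log µg/kg) so almost all contaminated samples are
  quantifiable; sub-LOQ draws are emitted censored.
* **Seeds** expand to per-stage child seeds through a documented
  counter scheme (`chemvalid:::child_seed`), so each stage is
  independently reproducible and all derived seeds stay below $2^{31}$.

What passing tests on these simulations demonstrate is *statistical*
correctness of the machinery — unbiased coefficients, calibrated
lack-of-fit and type-I rates, recovery of a planted boundary optimum in
≥ 90 % of seeds. They do not show that real extracts follow Gaussian
noise, that real recovery surfaces are quadratic, or that real matrix
effects are proportional across the calibration range; those are
modeling idealizations.

## Numerical choices and problem sizes

Tie-breaks (smallest coded norm, then factor order) make optimizer
output deterministic; effects and fits are invariant to run-order
permutation; coding round-trips to machine precision. Monte-Carlo
checks in the test suite and acceptance script use 200–4000
replicates per property and 100 end-to-end workflow seeds — sizes at
which the binomial/standard-error bands quoted in the tests are
comfortably resolved on a single CPU.

## Known limitations

Two-sided (target-is-best) and smaller-is-better desirability branches
are not implemented; no LOD model (censoring is taken as reported); no
top-down (reproducibility-based) uncertainty route; no peak
integration or instrument-file parsing — inputs are post-quantification
tables; ridge/canonical analysis of stationary points beyond the
axis-aligned closed form is out of scope.
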