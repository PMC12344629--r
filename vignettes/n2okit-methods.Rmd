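---
title: "Methods and design notes for n2okit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for n2okit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2okit)
```

`n2okit` implements the analysis chain of chamber-based soil N₂O studies as
independent, composable stages. This vignette documents the models each
stage assumes, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
known limitations.

## Chamber flux estimation

A static chamber (or sealed microcosm jar) accumulates soil-emitted N₂O in
its headspace; under the linear-accumulation assumption the mixing ratio
grows linearly over the short closure (typically 20–40 min, 3 samples). The
flux is

$$F = \frac{\Delta g}{\Delta t}\cdot d \cdot \frac{T_0}{T}\cdot \frac{V}{W}$$

with $\Delta g/\Delta t$ the fitted slope, $d$ the N₂O density at standard
conditions, $T$ the closure temperature, $V$ the headspace volume and $W$
the soil mass (field chambers divide by footprint area $A$ instead).

Design choices:

* **Input is a dry-air mole fraction (ppb).** Chamber samples are measured
  against ppb calibration standards, so the implementation defines the
  slope in ppb min⁻¹ and converts to a mass concentration with
  $d = M/V_m$ ($M = 44.013$ g mol⁻¹, $V_m = 22\,414$ cm³ mol⁻¹, so
  $d \approx 1963.6$ g m⁻³) and the ideal-gas factor $T_0/T$. This makes the
  unit chain dimensionally coherent end to end; $d$, $T_0$ and $T$ are all
  explicit configuration values, never inferred.
* **Slope by ordinary least squares over all samples.** With the standard
  3-point design, OLS is the natural estimator; no $r^2$ rejection filter is
  applied by default, but $r^2$ is reported on every fit so users can impose
  a QA cut-off (common practice uses $r^2 \ge 0.9$ for 3-point closures).
  A 2-point closure is admitted and is exact by construction.
* **Headspace volume is always explicit.** Jar headspace (jar volume minus
  soil volume) and field-chamber effective volume depend on packing and
  installation; no default geometry is shipped, and `chamber_geometry()`
  validates the basis (soil mass vs area) against the supplied fields.
  Closure temperatures outside 250–330 K are rejected unless explicitly
  overridden.

Cumulative emissions integrate the (daily-scale) flux series between
sampling dates as $\sum_i R_i D_i$, with $R_i$ the mean of the two bounding
fluxes (trapezoid rule, i.e. linear interpolation between sampling dates)
and $D_i$ the interval length. The rectangle (left-endpoint) rule is
available only as an explicit alternative. Unit hooks convert hourly fluxes
to daily (×24) and per-area µg m⁻² totals to kg ha⁻¹ (×10⁻⁵) *before*
integration. Integration is exactly additive over concatenated intervals and
partition-invariant for constant series; both properties are tested.

Nonlinear (HMR-style) chamber models, other gases and gap-filling beyond the
linear interpolation are out of scope.

## Agronomic metrics

* WFPS (%) $= 100\,\theta/(1-\rho_b/\rho_p)$, with particle density
  defaulting to the mineral-soil value 2.65 g cm⁻³. WFPS > 100% warns
  (supersaturation) rather than fails, since sensors can report it.
* YSNE (kg N₂O Mg⁻¹) divides seasonal cumulative emission by dried crop
  yield. In summary tables YSNE is aggregated **ratio-then-mean**: a
  treatment's across-year YSNE is the mean of its yearly ratios, matching
  how published tables are built (mean-then-ratio gives different numbers
  whenever yield varies between years, and is deliberately not offered).
* Treatment means across years average the yearly *cell means*, not pooled
  plots, so unbalanced replicate counts cannot weight one year more.
* Report-layer rounding is **half away from zero** at the printed precision
  (e.g. 0.685 → 0.69), applied only when `digits` is requested; internal
  values keep full precision. A `sqrt(.Machine$double.eps)` nudge protects
  exact decimal halves from binary-representation underflow.
* Net ion consumption between two incubation time points is early − late
  (positive = consumption), matching the convention that electron-acceptor
  drawdown is a positive consumption.

Reconstruction limits: when a published table is rebuilt from its *printed*
cells, cells that the original authors computed from unrounded plot-level
data can disagree in the last digit. With the bundled two-year field cells
(`field_summary_cells()`), all cumulative-emission means and the acceptance
YSNE quantities reproduce exactly; a few YSNE cells (e.g. 4.55/6.74 = 0.675
printed as 0.67) and the year-1 yield mean (7.005 from printed cells vs
7.16 published) differ in the second decimal for that reason. The package
reports what the printed inputs imply and does not attempt to match
unrounded source data it does not have.

## Isotopomer source attribution

N₂O is a linear N–N–O molecule; the central (α) and terminal (β) nitrogen
sites fractionate differently between microbial pathways. From the two site
deltas (‰ vs AIR-N₂):

$$\delta^{15}N^{bulk} = \tfrac{1}{2}(\delta^{15}N^\alpha + \delta^{15}N^\beta),
\qquad SP = \delta^{15}N^\alpha - \delta^{15}N^\beta,$$

and the inverse map $\delta^\alpha = bulk + SP/2$, $\delta^\beta = bulk -
SP/2$ lets measurements be entered in either parameterisation (the round
trip is tested to machine precision). δ¹⁸O is referenced to VSMOW.

**Ambient correction.** Headspace gas is a two-pool mixture of background
air and soil-emitted N₂O. For each delta axis,
$\delta_{obs} C_{obs} = \delta_{amb} C_{amb} + \delta_{soil} C_{soil}$ with
$C_{soil} = C_{obs} - C_{amb}$, solved for $\delta_{soil}$. Because the
balance is linear in δ, correcting α and β and recomputing SP is identical
to correcting SP directly; both routes are implemented and their equality is
tested, so either convention can be cited. The correction requires
$C_{obs} > C_{amb}$ and degrades gracefully: as $C_{amb} \to 0$ it converges
to the identity (tested at $C_{amb} = 10^{-6} C_{obs}$). No ambient
reference values are hard-coded — the appropriate background (e.g. a
hemispheric annual mean for the sampling year) is a calibration input.

**Classification.** End-member domains are axis-aligned boxes in
(SP, δ¹⁵N^bulk, δ¹⁸O) space; published compilations give rectangular
ranges, and polygon support is deliberately out of scope. A signature's
membership is every box containing it on all supplied axes (overlaps are
reported, not resolved); outside all boxes, the nearest domain by Euclidean
box-edge distance (per-axis scaling available, default 1 ‰ per unit) is
reported, and distance is zero exactly when membership is non-empty. No
end-member values ship with the package: the configuration template carries
clearly labelled synthetic placeholders that must be replaced from the
user's cited compilation.

**Uncertainty.** Instrument precisions default to 0.2‰ (bulk), 0.3‰ (δ¹⁸O)
and 0.5‰ (each site delta), typical of continuous-flow IRMS. Monte-Carlo
propagation perturbs α, β and δ¹⁸O with independent Gaussians and re-runs
the correction per draw. Independence is an approximation: real α/β errors
are partially correlated through calibration, which is why the bulk
precision (0.2‰) is better than the $0.5/\sqrt 2 \approx 0.35$‰ implied by
independent site noise; the reported bulk SD should therefore be read as
conservative. With no ambient dilution the SP standard deviation has the
closed form $\sqrt{\sigma_\alpha^2+\sigma_\beta^2} \approx 0.707$‰, which
the MC reproduces within 2% at $10^5$ draws (tested). Quantitative
multi-source Bayesian partitioning and N₂O-reduction fractionation vectors
are out of scope; `mixing_fraction()` provides only the generic linear
two-endmember interpolation.

## Group statistics

One-way ANOVA is computed through `stats::lm`/`stats::anova` and checked in
the tests against an explicit sums-of-squares oracle. Pairwise comparisons
use Fisher's LSD with omnibus gatekeeping: pairs can only be significant
when the omnibus F has $p < \alpha$ (default 0.05), and then pair $(i,j)$ is
significant iff $|\bar x_i - \bar x_j| > t_{1-\alpha/2,\,df_w}
\sqrt{MSE\,(1/n_i + 1/n_j)}$. No further multiplicity correction is applied
— the protected-LSD convention of agronomic field tables. At $k = 2$ the
procedure reduces exactly to the pooled two-sample t test (tested). The
degenerate all-constant input (zero variance everywhere, equal means) is
rejected with a clear error rather than returning lm's unreliable
perfect-fit F.

Compact letters use insert-and-absorb: start from one class holding all
groups, split every class containing both members of each significant pair,
absorb subset classes, then label classes 'a', 'b', … ordered so that the
group with the largest mean carries 'a' (ties broken by input order,
deterministically). Validity (shared letter ⇔ not significantly different)
is property-tested over random significance patterns, and the canonical
patterns (all same, all different, only-extremes-differ → a/ab/b) are pinned.
Under the null the family-wise any-significant-pair rate of the gatekept
procedure tracks the omnibus α; the test suite verifies 5% ± 1 percentage
point over 10⁴ simulated null datasets at the replicated-field design
(4 treatments × 4 plots).

## Response-ratio meta-analysis

Each literature record contributes RR = 100·(treatment − control)/control
(percent change; negative = mitigation). The natural-log response ratio is
available behind `type = "log"` for cross-study comparability but is never
the default, because percent change is the scale on which such summaries
are reported. Records are unweighted — with cumulative emissions extracted
from heterogeneous publications, per-record variances are unavailable, so
the summary is a one-sample t on the RRs: mean, SD, the
$t_{n-1}$ CI, the two-sided p of mean = 0, and the fraction of negative
effects. The CI machinery is verified against `stats::t.test` and the
type-I error of the test at the null is checked at 5% ± 1 point over 10⁴
simulations. Control-arm selection (same N fertilisation as the treated
arm) is data-preparation guidance, not code; publication-bias diagnostics
are out of scope.

## Synthetic-data generators

Every generator is a deterministic function of (configuration, seed), uses
`withr::with_seed` so the caller's RNG stream is untouched, and is the exact
inverse of its analysis stage at zero noise (the round-trip suite covers the
flux equation, the cumulative integral, YSNE and the isotope mass balance at
≤ 10⁻¹⁰ relative error).

* `simulate_chamber_series()` inverts the flux equation to a ppb min⁻¹
  slope and adds Gaussian instrument noise per sample. Defaults emulate the
  microcosm design: samples at 0/10/20 min and a 330 ppb baseline near the
  tropospheric background (field chambers: pass 0/20/40 min).
* `simulate_field_season()` uses a double-peak Gaussian baseline curve keyed
  to a split fertilisation (peaks near 17% and 50% of a 120-day season) —
  the shape is a documented modelling choice, not an estimate — with
  multiplicative treatment effects and mean-one lognormal plot noise
  (default CV 0.2, four plots per treatment, mirroring a randomized
  complete block field design).
* `simulate_isotope_mixture()` applies the forward mass balance exactly,
  then instrument noise.
* `simulate_meta()` draws RRs from a Normal with the requested mean and SD
  (defaults −9% and 28.4%, a realistic sulfate-effect population) and fixes
  controls at 100 units so the drawn RR is recovered exactly.

What the generators do *not* emulate: nonlinear chamber saturation,
autocorrelated seasonal weather driving flux peaks, correlated α/β
instrument errors, inter-study heterogeneity structure (the meta population
is a single Normal), or non-detects. Passing round-trip tests therefore
demonstrates the correctness of the arithmetic chain, not robustness to
those real-data features.

The test suite and acceptance script keep simulation sizes modest by
design: 10⁴ replicates for type-I-error checks (binomial SE ≈ 0.2
percentage points), 10⁵ draws for the Monte-Carlo closed-form comparison,
and a 76-record synthetic effect population matching the reported
literature-review size.

## I/O and reproducibility

CSV schemas are fixed (comma, '.' decimal, UTF-8, ISO-8601 dates, header
required) and validated with errors naming the missing column or offending
closure. Configuration is one YAML file whose sections are validated by the
same constructors the R API uses, so a config error carries the same
message a direct call would. All outputs are deterministic given inputs,
configuration and seeds; JSON is written with full precision
(`digits = NA`). The command-line wrapper distinguishes validation errors
(exit 2) from unexpected/I-O errors (exit 3).
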