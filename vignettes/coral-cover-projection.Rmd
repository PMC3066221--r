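---
title: "Methods: coral cover projection under warming and acidification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral cover projection under warming and acidification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the method left room. It states no
empirical results beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The modelling problem

Shallow-water reef corals face two coupled climate pressures: episodic mass
mortality when summer temperatures exceed a site's bleaching threshold, and
a slow erosion of calcification as rising CO2 lowers the aragonite
saturation state (Ω_a) of surface seawater. Projecting coral cover at a
site therefore needs (i) site-scale SST projections — which raw climate
models do not provide credibly, because their 20th-century runs can carry
multi-degree mean biases and distorted seasonal amplitudes — and (ii) an
annual growth/mortality bookkeeping that couples temperature, carbonate
chemistry and bleaching. The package implements both, plus the ensemble
machinery that turns many imperfect projections into probability
statements.

## Annual cover model

Cover is tracked relative to its start-year value (`C = 1` at the start).
Each year:

1. the adapted bleaching threshold is evaluated,
2. degree heating months (DHM) are accumulated over the calendar year,
3. the annual mean temperature drives the cubic growth curve,
4. Ω_a is interpolated from the (temperature, pCO2) table,
5. the update `C' = C (1 + τ G(T̄) A(Ω) − m0) (1 − M(DHM))` is applied,
   floored at zero.

The background mortality `m0 = τ G(T̄₀) A(Ω₀)` is calibrated once so that
start-year climate is at equilibrium: growth and mortality balance and a
stationary climate holds cover at exactly 1 (this is an invariant the test
suite checks to 1e-9 over a century).

The exact form of the annual update is a design decision: the multiplicative
growth–mortality balance with the episodic cull applied as an annual
fraction is the simplest scheme consistent with (a) the start-year
equilibrium assumption, (b) trajectories that show sharp vertical drops in
bleaching years with geometric recovery between events, and (c) the
possibility of relative cover exceeding 1 where warming moves a cool site
toward its growth optimum. Growth is applied before the episodic cull by
default; the order is configurable (`mortality_order`) and the equilibrium
invariant holds under both orders. There is no cover ceiling, only a floor
at 0.

### Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `baseline_turnover` (τ) | yr⁻¹ | 0.05 | gross growth scale at equilibrium; implies decadal-scale recovery from a major mortality event |
| `omega_sensitivity` (s) | per Ω-unit | 0.3 | fractional calcification loss per unit Ω_a decline; 0–0.45 is the swept range |
| `adaptation_rate` | °C / century | 0 | linear drift of the bleaching threshold; 1 °C/century is the optimistic bound, 2 the sweep maximum |
| `delta_low`, `delta_high` | °C | 5 | offsets placing the zero-growth anchors around the climatological extremes |
| `sd_mult` | – | 2 | optimum sits this many climatological SDs below the warmest month |
| `growth_floor` | – | −1 | clamp on negative (net-decline) growth outside the calibrated range |
| threshold offset | °C | 1 | bleaching threshold above the warmest climatological month |

## Growth curve

The cubic is solved exactly from a 4×4 linear system (two zeros, zero
derivative and unit value at the optimum). Normalising the peak to 1 makes
the curve purely *relative*; the absolute rate enters only through τ. If a
perturbation draw breaks the anchor ordering the fit raises a classed
infeasible-curve error carrying the draws — ensembles exclude and log such
members rather than silently retrying, so the instability rate is itself an
observable. Negative growth beyond the zero-growth temperatures is
permitted but clamped at `growth_floor`; this keeps runs that stray far
outside the calibrated temperature range bounded while preserving the
qualitative instability (occasional runaway members at high-variability
sites) that the sensitivity protocol is designed to expose.

`clim_sd`, the "standard deviation" in the optimum anchor, is read as the
SD of the 12 climatological monthly means — the enclosed quantity in the
anchor definition is the monthly climatological mean. The alternative
reading (interannual SD of the warmest month) is exposed as
`sd_mode = "interannual_warmest"` in `monthly_climatology()` but is not the
default.

## Carbonate chemistry

Ω_a is computed from the (pCO2, total alkalinity) pair by solving total-scale
alkalinity balance for [H⁺] with `uniroot` on the bracket pH 2–12
(tolerance 1e-18), using Weiss K0, Lueker K1/K2, Dickson KB, Millero KW,
Mucci aragonite Ksp, Uppström borate and Riley–Tongudai calcium. Phosphate
and silicate alkalinity are neglected (oligotrophic surface water). The
default table spans 15–35 °C × 200–1100 µatm at salinity 35.

Default total alkalinity is 2400 µmol/kg. This is a deliberate calibration
choice: with these constants it reproduces the canonical open-ocean
subtropical surface anchor points — Ω_a ≈ 3.8 at (25 °C, 370 µatm) and
≈ 2.5 at (25 °C, 700 µatm) — that the projection framing is built around.
(At 2300 µmol/kg the same solver gives ≈ 3.5 and ≈ 2.3.) Both salinity and
alkalinity are exposed in the table constructor. Lookup is bilinear and
refuses to extrapolate outside the grid hull.

A strictly linear per-unit sensitivity is implemented: `s = 0.3` over a
3.8 → 2.5 Ω_a decline gives a 39 % calcification cut, not 30 % — the
per-unit definition is taken at face value rather than being rescaled to
match a rounded "about 30 %" gloss.

## Episodic mortality

DHM accumulate per calendar year (an annual model step, not a rolling
window). The mortality quadratic has zero intercept by design: bleaching
events near zero DHM kill essentially nothing, and a positive intercept
would erode cover every stress-free year. A free-intercept variant exists
for fit comparison only. Threshold adaptation shifts only the episodic
threshold, never the growth curve.

The three packaged observation tables (`all_data`, `mhi_nwhi`, `carib`)
are synthesized — the underlying event observations are not published as
machine-readable tables — and are constructed to match the documented
qualitative ordering: the Caribbean-2005-style curve is steepest, the
Hawaiian curve mildest, the pooled curve in between. Filenames and
documentation mark them synthetic; fitted coefficients from them should
not be quoted as observational results.

## Downscaling

Selection: a run passes when |mean bias| < 3 °C *and* the
seasonal-amplitude difference < 1, both strict inequalities; a run with
bias exactly 3 °C fails. "Seasonal amplitude" is operationalized as the SD
of the detrended residuals — exactly the quantity the CDF map rescales —
and the 1-SD limit means the model residual SD differs from the historic
SD by more than one historic SD (relative difference ≥ 1). Both limits are
arguments.

The transform detrends with a 4th-order polynomial in fractional year,
centered at the series midpoint and scaled to decades so the normal matrix
stays well-conditioned. One pooled residual distribution per series is used
for the CDF map (the per-month distributions appear only in the Monte Carlo
generator, where the method states them per month). The map clamps CDF
probabilities to [1e-15, 1 − 1e-15] before inversion to avoid infinities in
the far tails; under normality the map is algebraically the linear rescale
`(r − mean)·σ_hist/σ_model`, and the tests verify the two paths agree to
machine precision.

The low-pass filter for the multi-model trend is unspecified by the method
description; a 25-month centered moving average with edge reflection is
used — simple, deterministic, and attenuating the 12-month cycle to ≤ 1/25
of its amplitude (a Dirichlet-kernel bound the tests verify as a <10 %
residual-cycle invariant). Method 2 averages *bias-corrected only* series
(not seasonally rescaled ones), switchable via which series are passed in.

Note that a 4th-order fit to a finite record of a pure seasonal cycle is
not exactly its mean: the polynomial wiggles near the record edges (up to a
few tenths of a degree on a 20-year sinusoid). This is inherent to the
defined method, and the tests assert SD-based bounds rather than pointwise
equality.

## Ensembles and probabilities

Member `k` of any seeded ensemble draws from the substream
`derive_seed(seed, k)` (a Lehmer-style hash kept below 2³¹), so members are
independent and individually reproducible; identical seeds give
bit-identical ensembles. Decline probabilities use the sample mean/SD
normal fit of member end-states — no robust variant — and degenerate
(zero-variance) member sets return 0/1 by mean position. Evaluation years
default to 2050 and 2099. Probabilities are computed from individual-model
members when both methods are available; that choice is a switch, not a
hard-coding.

The preset cases are: `less_resilient` (adaptation 0, s = 0.3),
`more_resilient` (adaptation 1 °C/century, acidification off),
`no_bleaching` (episodic module off, otherwise as less-resilient — the
composition of the unstated remaining parameters is a design decision
here), and `validation_20c` (less-resilient parameters on a 1900–1999
window).

## Sensitivity protocol

One parameter is swept while everything else is held at the less-resilient
baseline; every level reuses the same member substreams (common random
numbers), so level-to-level differences are parameter signal, not sampling
noise. The metric is the normalized variance — *population* variance
divided by mean — of the per-level ensemble means, and separately of the
per-level member SDs, at 2050 and 2099. "Approximately 200 runs" is read
as the total across a parameter's levels (configurable), split evenly.
Members whose absolute cover change exceeds 500 % anywhere are flagged
unstable; summaries are reported with and without them, and the unstable
rate is part of the report.

## Synthetic data: what it emulates, and what it does not

The generator produces monthly SST as climatology + linear (optionally
quadratic) trend + independent per-calendar-month Gaussian noise;
model-style series add a mean bias and multiply the seasonal anomaly by a
factor. This reproduces the statistical features the downscaling stage is
designed to remove and the Monte Carlo stage to reproduce — and nothing
else. Not emulated: interannual autocorrelation (ENSO-like persistence),
spatial structure, trend breaks, or frontal-zone variability. Passing tests
therefore demonstrate correct recovery of *this* statistical structure, not
skill on real reconstructions; with real data the pooled-residual normal
assumption and the independence of monthly draws are the first places to
look for misfit. An AR(1) hook was considered and deliberately left
unimplemented: no autocorrelation structure is specified anywhere in the
source method, and silently inventing one would change the Monte Carlo
spread.

The four site presets (JOH/OAH/FFS/MID) are illustrative fixtures ordered
qualitatively (MID coldest, largest seasonal range and variability); they
are not extracted reconstruction values. The default CO2 preset is a
logistic 370 → 700 ppm rise over 2000–2099 — chosen because, through the
default aragonite table, it spans the Ω_a ≈ 3.8 → 2.5 century-scale
decline. The logistic is rescaled to hit its endpoints exactly, which keeps
it symmetric about the window midpoint.

The per-run selection-statistics fixture (41 rows over 20 model families,
of which exactly 17 fail the strict screening rules) is likewise synthetic,
constructed to reproduce that composition — including a boundary run with
bias exactly 3 °C — because the original evaluation table is not available
in machine-readable form.

## Numerical choices and degenerate inputs

* Calendar validation: a gap or duplicate month is an error naming the
  first offending (year, month); readers sort before validating, so
  climatology is invariant to on-disk ordering.
* The growth-curve 4×4 solve and the mortality quadratic use exact linear
  algebra / `lm`; coefficient recovery from noise-free data is tested at
  1e-9 relative error.
* Zero residual variance, zero `clim_sd`, single-point mortality tables,
  empty selection tables, out-of-hull Ω_a queries and pre-start policy
  years all raise classed errors rather than returning NA.
* `fit_detrend` requires at least `order + 1` years and errors on rank
  deficiency.
* Equilibrium infeasibility (start-year mean outside the positive-growth
  range) is a classed error; ensembles exclude and log such members.

## Problem sizes

The test suite runs Monte Carlo ensembles of 100 members for the
case-ordering check, 500 + 250 members for the spread-convergence check,
and 50-run sensitivity sweeps (10 members per adaptation level); the
suite completes in well under a minute. These sizes were chosen as the
smallest at which the corresponding statistical properties are stable;
production use would run the full 500-member ensembles and ~200-run sweeps
the defaults encode.

## Known limitations

* Annual time step: no sub-annual bleaching dynamics, recovery lag, or
  symbiont shuffling; adaptation is a threshold drift only.
* No recruitment/connectivity between sites, no taxonomic succession, no
  light/turbidity or local anthropogenic stressors.
* Carbonate chemistry is open-ocean: no reef-scale alkalinity depletion,
  crustose-coralline-algae response, or cementation effects.
* Monthly SST values are independent draws in the synthetic world; real
  records are autocorrelated, so synthetic-based DHM frequencies are, if
  anything, optimistic about the clustering of stress years.
* NetCDF input is not supported in this implementation (CSV only); the
  CSV dialect is `year,month,sst_c`.
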