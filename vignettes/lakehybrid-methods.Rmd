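---
title: "Hybrid empirical-parametric modelling of deep-lake oxygen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid empirical-parametric modelling of deep-lake oxygen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lakehybrid)
```

## The problem

Deep monomictic lakes receive oxygen at depth almost exclusively through
intermittent winter mixing; the rest of the year the deep water loses oxygen
to the decomposition of settling organic matter. Management of such lakes
has historically treated the nutrient-chlorophyll-oxygen chain as a fixed
set of relationships, but under remediation (reoligotrophication) the
relationships themselves drift: phosphorus limitation switches on only once
phosphorus becomes scarce, and the oxygen cost of a unit of algal biomass
changes as the food web reorganizes. A model with frozen coefficients is
therefore only valid near the states it was fitted in, while a fully
mechanistic model of the shifting biology is unidentifiable from monitoring
data alone.

`lakehybrid` implements a hybrid strategy: the physical oxygen *source*
(winter mixing, gas exchange, river underflow) is a small parametric
two-box model, while the biogeochemical oxygen *sink* (summer depletion)
is forecast by empirical dynamic modelling (EDM) — locally weighted (S-map)
regression on a multivariate delay embedding, whose coefficients are free
to vary with the system state. The two halves alternate seasonally and are
iterated over decades, and a scenario engine runs the coupled model across
a grid of warming offsets and constant phosphorus levels to compute a
regulatory hypoxia benchmark (percent of time deep oxygen sits below
4 mg/L).

## Empirical dynamic core

**State-space reconstruction.** An embedding is a list of
(variable, lag) coordinates; `state_matrix()` builds the row-per-time-point
matrix, z-normalizing each coordinate with statistics taken from library
rows only, so distances are scale-free and forecast skill is invariant to
affine rescaling of any input (`regularize()` first puts ragged monitoring
archives on a uniform monthly grid, bridging gaps of at most `max_gap`
steps by linear interpolation and never imputing inside the embedding).

**Simplex projection** forecasts a target as the weighted mean of the
`E + 1` nearest library neighbours, with weights `exp(-d_i / d_min)`.
Zero-distance neighbours receive weight one and suppress all others;
neighbour ties break toward the earlier time index, making every forecast
deterministic. Leave-one-out evaluation excludes library rows within an
exclusion radius (default: the largest lag in the embedding) of the
prediction row to prevent leakage through temporally overlapping vectors.

**S-map regression** fits, at every prediction time, a weighted linear
regression of `target(t + tp)` on the embedding coordinates plus an
intercept, with library weights `w_i = exp(-theta d_i / dbar)` where `dbar`
is the mean library distance to the target state. The solve uses the SVD;
rank-deficient designs fall back to the minimum-norm solution with a
warning. At `theta = 0` all weights are equal and the procedure reproduces
a single global least-squares (multivariate autoregressive) model exactly —
the test suite checks agreement with `lm()` to 1e-8 — while growing `theta`
makes the fit increasingly local, i.e. state-dependent. `theta_scan()`
evaluates leave-one-out skill over a grid (default: 0 plus a log-spread up
to 10); a clear gain at some `theta > 0` is the operational definition of
nonlinear state dependence, and its absence on linear-stochastic (MAR)
input is the corresponding null result.

**Interaction tracking.** With a mechanistic embedding — one containing
the key causal variables — the local regression coefficients approximate
the Jacobian elements of the dynamics. `interaction_coefficients()`
rescales them to raw units (per-coordinate standard deviations divide out),
and `bin_interactions()` summarizes them against a conditioning variable in
equal-count bins (default 10) with bootstrap intervals. Two caveats are
documented behaviour, not bugs: coefficients are only interpretable where
the interaction is dynamically active (the chlorophyll effect on deep
oxygen is structurally zero during the mixing season, so the package's own
validation correlates that coefficient with truth over the stratified
season only), and coefficient series at library edges shrink toward the
library mean, as any local regression does.

**Embedding comparison.** `sequential_embedding_comparison()` scores a
baseline embedding (typically the physical drivers: mixed-layer depth,
surface temperature, air temperature, discharge) and then each successive
augmentation by biogeochemical candidates, each at its best theta. A
variable that genuinely drives the target raises best-theta skill; a noise
variable does not.

## Convergent cross-mapping

`ccm()` tests whether a putative cause can be estimated from the effect's
delay embedding with skill that rises as the library grows. The embedding
dimension `E*` maximizes cross-map skill at horizon `tp = 0` over
`E` in [1, 15]; skill is then measured at `tp = floor(-E*/2)` — anchored at
the middle of the embedding vector — which penalizes dimensions selected by
overfitting. Library subsampling is random without replacement (100
subsamples per size by default; contiguous segments optional).

The convergence verdict is deliberately conservative. Raw skill curves
rise with library size for *any* nonzero-skill relationship — including the
reverse direction of a strongly forced pair, whose history genuinely
carries information about its driver (generalized synchrony), and any
finite-sample estimate. The verdict therefore requires (i) terminal skill
above the 95th percentile of a phase-randomized (Ebisuzaki) surrogate null
that preserves the cause's amplitude spectrum — hence its seasonal cycle —
and (ii) a small-to-large-library rise exceeding the null's own rise by
more than `delta` (default 0.1). On one-way coupled chaotic maps (coupling
0.32) this yields a convergent verdict in the true direction only in most
realizations, with the reverse map markedly weaker (terminal skill roughly
0.4-0.5 against 0.98). The reverse map's residual skill is genuine
synchrony information — a strongly forced variable's history partly
determines it, so an independent nonparametric regression recovers a
similar skill ceiling — and in occasional realizations its rise crosses
the threshold; the terminal-skill asymmetry is the robust discriminator.

On strongly seasonal series the seasonal surrogate null is intentionally
brutal: most of the cross-map skill between two seasonal variables is
reproduced by surrogates that share only the annual cycle, so few pairwise
links on the synthetic lake pass the strict verdict even when dynamically
real. This is a known limitation of cross-mapping on seasonal data; the
package reports terminal skill, critical values and the verdict separately
so users can apply the discrimination appropriate to their system.

## Two-box physics

`box_volumes()` integrates a depth-area table (trapezoid rule) above and
below the box boundary. Oxygen solubility follows the Benson-Krause
freshwater relation with an optional pressure correction. One winter day
(`winter_mix_step()`) applies, in order: convective homogenization of the
column above the day's mixing depth (volume-weighted, exactly
mass-conserving; deep renewal occurs only when mixing reaches below the
boundary), exact exponential relaxation of the upper box toward saturation
(gas exchange velocity `k_gas`, default 1 m/day), and river underflow —
in winter the cold river plunges and displaces deep water with water
saturated at river temperature, as a replacement flux `Q x dt`. The summer
surface update integrates a linear ODE exactly: relaxation to saturation
plus a chlorophyll-proportional net production term confined to the photic
zone (20 m by default) and diluted over the box depth; any alternative
rate law can be swapped in through `production_fun`, since the published
parameterizations of surface oxygen vary between lakes. `rebox()` moves
the box boundary with conservative entrainment/detrainment where a
seasonally migrating interface is wanted.

The hybrid simulator keeps the box boundary at a fixed deep reference
horizon `z_deep` (default 250 m, the depth conventionally defining a
full-renewal winter), so the deep box is the stratum whose oxygen the
deep-water predictors are trained on: it is renewed by the rare deep-mixing
events and the river underflow, not by ordinary winter ventilation of the
upper column. An earlier design that tracked the seasonal mixed layer with
entrainment ventilated the deep stratum every winter and suppressed
hypoxia entirely; the fixed-horizon geometry reproduces the observed
regime of multi-year oxygen declines punctuated by mixing years.

## The hybrid loop

`run_hybrid()` starts at the first May of the forcing (initial surface and
deep oxygen from the configuration; biogeochemical states default to
training means) and then alternates: November-April daily physics for both
boxes; May-October monthly iteration of three S-map predictors (deep
oxygen, chlorophyll, surface phosphorus), each fed the current predicted
state plus the exogenous drivers (physics variables, lake phosphorus, air
temperature) refreshed from the forcing each step. Normalization constants
are frozen from training; predictions never re-anchor to observations. At
the end of October the empirically predicted deep oxygen is handed back to
the physics as the deep box's initial condition; at the end of April the
physics hands deep oxygen back to the predictors. Monthly iteration (six
steps per 180-day stratified season) matches the cadence the predictors
were trained on. States that leave the training library's neighbourhood by
more than a configurable normalized nearest-neighbour radius flag the run
as an extrapolation.

The default predictor embeddings pair each target with its direct drivers
at lag zero, using air temperature as the seasonal coordinate: air
temperature is in phase with the seasonal insolation/stratification cycle,
whereas surface water temperature lags it by about a month, and an S-map
conditioned on the lagged proxy acquires a spuriously steep temperature
response that inflates scenario depletion. `fit_hybrid_predictors()`
accepts any alternative embedding (for example one chosen by
`sequential_embedding_comparison()`), a training cutoff date so simulations
never see their own future, and `force_theta = 0` for the fixed-coefficient
linear ablation used as a baseline.

## Scenario engine

`detrend_offset()` removes the OLS linear trend from air temperature
(preserving mean and seasonal cycle) and adds a uniform offset;
`make_grid()` builds the offset x phosphorus grid (defaults 0/1/3 degC by
65 down to 15 ug/L in 1 ug/L steps, 153 scenarios) in a deterministic
order. `run_grid()` regenerates the surrogate forcing per scenario and runs
the hybrid model at the scenario's constant phosphorus. The meteorological
random stream derives from the master seed and the phosphorus level only,
so the temperature variants of a scenario share one weather realization and
differ purely by the imposed offset — the analogue of re-driving the same
detrended historical meteorology under different offsets — which also makes
the warming comparison a paired one: with a shared uniform-draw stream, the
set of deep-mixing winters under +3 degC is a subset of those under 0 degC.
`hypoxia_fraction()` computes the benchmark as percent of time strictly
below 4 mg/L, weighting by interval length when the series is unevenly
spaced. Scenario failures are caught per scenario and reported in the
output table rather than aborting the grid.

## The synthetic lake: what it emulates and what it does not

`simulate_lake()` is a discrete-time monthly process model — not a fixture
file — whose update map (`lake_step()`) is exposed together with analytic
Jacobians so that every downstream claim can be checked against ground
truth. It emulates, by construction: seasonal forcing (insolation weight
`l(month)`, air-to-surface temperature transfer, alpine discharge);
intermittent deep-mixing winters whose probability falls with the winter
air-temperature anomaly through a logistic link; a multi-decadal
phosphorus remediation trend (half-cosine from 62 to 14 ug/L over 37
years: slow onset, rapid mid-course decline, levelling off — a shape that
also gives an empirical analysis comparable library coverage of both
trophic extremes, which controls which parts of the state space an S-map
can learn); saturating (Michaelis-Menten) chlorophyll growth, so the
phosphorus effect on chlorophyll is near zero in the eutrophic state and
grows under phosphorus limitation; and a deep-oxygen sink with two
state-dependent components — an eutrophic legacy demand switched on by a
logistic threshold near 50 ug/L, and a chlorophyll export term gated by a
logistic export fraction that rises as phosphorus falls (near 22 ug/L).
The sum makes total summer depletion U-shaped in phosphorus with a minimum
near 35-45 ug/L and both arms below 0.02 mg/L/day; the chlorophyll effect
on deep oxygen is near zero at high phosphorus and distinctly negative at
low phosphorus.

The generator does not attempt a literal lake: no vertical resolution, no
phytoplankton composition, no ice, no sediment module, and noise levels
(process noise 0.6 ug/L chlorophyll, 0.5 ug/L phosphorus, 0.05 mg/L
oxygen; 2% observation noise) chosen so that structure is learnable but
not trivial. Passing the package's tests on this rig therefore shows that
the algorithms recover known structure of the stated kinds at realistic
signal-to-noise — not that any particular real lake behaves this way.
Jacobian-recovery correlations, in particular, vary by a few hundredths
across generator seeds (the chlorophyll-oxygen coefficient spans roughly
0.7-0.9); the reported checks fix the seed with the package defaults.

## Numerical choices and degenerate inputs

Distances are Euclidean on z-normalized coordinates; zero-variance
coordinates are an error (they cannot be normalized). Embedding rows with
any missing lag are masked, never imputed. The S-map requires at least
`E + 2` positively weighted library rows per prediction; `dbar = 0` (all
library states coincident with the target) is an error. Simplex ties break
by earlier time; `exclusion_radius = -1` disables the leave-one-out guard
(used when reproducing a global regression). Negative oxygen after a
physics step floors at zero with a warning. Seeds: every stochastic
component takes an explicit seed, restores the caller's RNG state, and
derives child streams via `derive_seed(master, label)` so adding scenarios
or reordering work never shifts existing results.

Problem sizes used by the shipped validation: 37-year monthly synthetic
lakes (444 points), coupled logistic maps of length 1000 with 50-100
library subsamples and 60-100 surrogates, 10^4-step mixing chains, and a
12-scenario (2 offsets x 6 phosphorus levels, 20-year) grid; these sizes
were chosen as the smallest at which the statistical contrasts of interest
are stable.

## Known limitations

The cross-map verdict on strongly seasonal data is conservative (see
above). S-map forecasts shrink toward the library mean outside the
training envelope — visible in scenario runs at phosphorus levels the
training trajectory visited only briefly — and the extrapolation flag
exists precisely because iterated prediction can wander there. The
two-box physics has no internal thermal model: it consumes thermocline and
mixing depths from a forcing file or from the built-in stochastic
surrogate, which reproduces regime statistics (seasonal cycles, mixing
frequency and its temperature response) but not any particular year. The
hybrid's surface box is bookkeeping above the deep horizon rather than a
resolved epilimnion; only the deep box is compared against data.
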