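---
title: "Modelling nocturnal bird migration as a fluid: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nocturnal bird migration as a fluid: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`birdflux` treats the nightly stream of migrating birds as a
two-dimensional fluid. The column-integrated (areal) bird density
ρ(x, t) in birds km⁻² and the flow velocity **v** = [v_lon, v_lat] in
km h⁻¹ satisfy a continuity equation with a source/sink term

∂ρ/∂t = −∇·(ρ**v**) + W,

where W in birds h⁻¹ km⁻² is the exchange rate with the ground: birds
taking off appear in the air column (W > 0), landing birds disappear
from it (W < 0). The assumptions this buys and their price:

* **Flow, not individuals.** ρ and **v** are averages over many birds;
  the model cannot represent two populations crossing the same cell in
  different directions, and individual speeds exceed the mean flow
  speed. This mirrors what a weather radar measures (volume averages
  over a 5–25 km radius), so nothing is lost relative to the data.
* **Mass conservation aloft.** Birds neither appear nor vanish in the
  air; every density change is advection or ground exchange. Mortality
  in flight and reproduction are ignored, which is why a year-round
  ground accumulation can go negative: autumn's departing juveniles
  were never "added" in the air ledger.
* **Closed accounting on a masked domain.** Wherever the data cannot
  support the model (day, rain, open water, high terrain, out of radar
  range), cells are masked and the mass they exchange with valid cells
  is booked explicitly as boundary flux rather than silently absorbed.

## Discretization

The equation is inverted, not integrated: given ρ at two consecutive
steps and the interface fluxes at the first, W follows algebraically
(forward-time, centred-space), so no stability condition applies to the
inversion itself. Specifics:

* **Staggered interfaces.** Cell-centred fluxes Φ = ρ**v** are averaged
  onto interfaces (arithmetic mean; one-sided at a boundary). The
  centred difference of interior interface values reproduces the classic
  (Φ(j+1) − Φ(j−1)) / 2Δ stencil.
* **Flux-form divergence.** Each interface flux is multiplied by its
  interface length and differenced; latitude-interface lengths are taken
  at the *edge* latitude (cos of the edge latitude × longitudinal step).
  Interior faces then cancel exactly in any domain sum, so the discrete
  mass balance — Σ Δ(ρ·area) = Σ W·area·Δt + Σ boundary·Δt — closes to
  rounding error on arbitrarily masked geometry, and the flux used in W
  is byte-identical to the flux reported as entering/leaving. The price:
  the scheme retains the spherical metric term (uniform meridional flow
  has divergence ρ·v·tanφ/R, the convergence of meridians), so the
  planar intuition "uniform flow ⇒ W = 0" holds exactly only for zonal
  flow. At 43–55° the term is below 0.1% of ρ per step.
* **Latitude-dependent cell widths.** Δlon in km shrinks with
  cos(latitude); cell areas and interface lengths carry this through
  (111.32 km per degree).
* **Attribution.** W over [t, t+1) is attributed to step t, and is
  computed only on cells valid at both instants; interfaces from a valid
  cell to a dynamically masked neighbour (rain, day) are recorded as
  `internal_boundary` fluxes rather than folded into W, so nothing is
  invented under rain.
* **Edges.** At the domain rim the one-sided cell-centred flux is used.
  The forward simulator therefore has an open boundary: outflow (and the
  matching inflow bookkeeping) is exactly what the inversion sees.

## Preprocessing parameters

* Contamination: profile cells with sd of radial velocity < 2 m s⁻¹ or
  airspeed < 5 m s⁻¹ are set missing (slow, weak scatterers: insects,
  snow). Both thresholds are conventional in radar aeroecology and
  configurable; airspeed requires wind-corrected speeds, so when no
  airspeed column exists the criterion must be disabled explicitly.
* Vertical integration: 200-m bins from 0 to 5000 m a.s.l.; bins below
  the local ground contribute nothing. The unobserved layer between the
  ground and the lowest bin with data is filled by `extend_lowest`
  (copy the lowest valid bin downward — adds low-altitude birds, the
  conservative choice for a layer where densities are usually highest)
  or `zero`. A fully missing profile stays missing: zero is information
  ("no birds"), absence is not, and the distinction matters to kriging.
* Velocities become eastward/northward components (direction measured
  clockwise from geographic north) and are density-weighted over bins;
  with no birds aloft the components are set to 0 rather than left
  undefined.
* Resampling to the model step time-averages density and
  vector-averages velocity; empty steps are flagged `missing`.

## Geostatistical interpolation and simulation

Densities are transformed to log(1 + ρ) (skewed, non-negative data) and
modelled as second-order stationary with a separable covariance
C(h, u) = sill · f(h/range_space) · f(u/range_time) plus a nugget at
the origin, f ∈ {exponential, gaussian, spherical}; distances are
great-circle km (the domain spans 12° of latitude, planar distance
would bias ranges). The nugget absorbs measurement error and micro-scale
variability and lets maps diverge from noisy data.

* **Fitting.** Weighted least squares on the empirical space–time
  variogram (site-pair × time-lag half mean squared differences, pooled
  into distance classes). Weights are fixed at n/γ̂²: putting
  model-dependent weights inside the objective rewards inflating the
  model variogram and collapses the fit to pure nugget.
* **Family choice.** The exponential family is the generic default, but
  its realizations are nowhere-differentiable in time; the flow model
  differentiates the field, so simulated roughness is amplified into
  spurious take-off/landing. For the smooth pulse fields of the wave
  scenarios the gaussian family (differentiable paths) is the
  appropriate model and is what their near-origin variogram supports.
  With a zero nugget the gaussian family is ill-conditioned, so the
  zero-noise benchmark keeps the exponential family for the kriging
  estimate, where path roughness is irrelevant.
* **Kriging.** Ordinary kriging per time step; the neighbourhood is
  every observation within `max_tlag_steps` (default 4) steps, so one
  factorization per step serves all cells. Singular systems fall back to
  a jittered solve, then to the neighbourhood mean, with a warning.
  Estimates are back-transformed (expm1, clipped at 0).
* **Simulation.** Aggregating the smooth kriging map biases sums, so
  aggregates are computed per conditional realization. Unconditional
  draws use the separability directly (Kronecker square roots: one
  spatial Cholesky over grid cells ∪ radar sites, one temporal Cholesky
  over active steps); sites coinciding with cell centres are aliased
  onto the cell to keep the joint covariance non-singular and the
  conditioning exact. Conditioning is by kriging with the same weights
  as the estimate (z_cond = ẑ + z_unc − ẑ_unc), so the ensemble mean is
  centred on the kriging estimate by construction; nugget noise is added
  at data points only. Everything is a pure function of (inputs, seed),
  and the caller's RNG state is restored.
* An optional nightly-mean trend (`trend = "nightly_mean"`) removes each
  night's global mean of the transformed data before kriging. With
  ordinary-kriging weights and neighbourhoods confined to one night it
  is exactly inert; it matters only when neighbourhoods straddle nights.

## Night assignment and masks

A (cell, step) is nocturnal when the solar elevation at the cell centre
is below 0° (geometric sunset; −6° civil twilight is a supported
alternative). Solar position uses the equation-of-centre ecliptic
algorithm (~0.01°); nights are labelled by the civil date of the evening
in local solar time, so a 02:00 step belongs to the previous evening's
night. Static validity: land, ≤ 2000 m a.s.l., within 150 km of a
radar. Dynamic validity: static ∧ night ∧ rain ≤ 1 mm h⁻¹ ∧ night not
excluded. Listed no-data nights are blanked before fitting and left
missing (no gap bridging).

## Aggregation

* Nightly pulse maps: per cell, Σ over the night's steps of the
  take-off (resp. landing) rate × Δt, in birds km⁻² and birds.
* Ground accumulation: per night, domain totals of take-off, landing,
  entering, leaving; nightly change = landing − take-off; cumulative sum
  from an arbitrary zero (the initial ground population is unknown).
  The identity "landing − take-off = entering − leaving" is a theorem of
  the discrete conservation law *when no birds are aloft at dusk and
  dawn*; the package checks the generalized form (with the aloft-change
  term) to 1e−6 relative and flags violations.
* Transects: the boundary interfaces are partitioned into six arcs named
  for the surrounding flyways (UK, North, East, Alps, Spain, Atlantic).
  Geometry is data — the shipped default splits a rectangular rim at
  mid-longitude (south) and mid-latitude (west); users supply their own
  table for real domains. Seasons: spring February–June, autumn
  August–December, by night label; both configurable.
* Ratios (autumn/spring route ratios, recruitment indices) use the
  dominant direction's seasonal total of a transect (or group), and the
  area-net recruitment divides the autumn deficit by the spring surplus.
  Because a ratio of ensemble means differs from the ensemble mean of
  ratios, the pipeline reports both, with Q5–Q95 from the per-realization
  ratios.
* Ensemble summaries are means with empirical Q5/Q95 (type-7 linear
  interpolation between order statistics).

## The synthetic generator

`wave_scenario()` is the study system the tests measure against: a
20 × 24-cell domain (44–49° N, 0–6° E) over six April nights at 15 min,
constant flow (16, 11) km h⁻¹, and two waves of 20 million birds, each
taking off on three consecutive nights at the previous night's landing
position (Gaussian pulses, σ = 70 km; raised-cosine take-off after
dusk; a hazard-ramp landing before dawn whose final step closes the
night at exactly zero aloft). Eight radars with multiplicative
lognormal noise (sd 0.2), an additive nugget (2 birds km⁻²) and 5°
angular noise emulate a realistic national network. Nightly bouts are
roughly 200 km — scaled down from continental bout lengths so a wave
stays trackable for three nights inside a desk-sized domain. The
forward run uses the same stencil as the inversion (round trips are
exact by construction), keeps the Courant number ≤ 0.5, and rejects
configurations where clipped negative mass exceeds 0.1% — FTCS is
weakly unstable for pure advection, so pulses are kept smooth (σ ≥ 2–3
cells) and horizons night-length.

What it does **not** emulate: wind drift and weather coupling, species
mixtures, altitude structure (the profile shape is collapsed before the
model anyway), nonstationary observation error, and real coastline or
terrain masks. Passing the recovery tests therefore shows the chain of
estimators is consistent, not that real radar data meet the model's
assumptions.

`dense_wave_scenario()` is the benchmark variant: 99 radars on a 9 × 11
lattice spanning the domain rim to rim, spacing ~64 km — below the
70-km pulse scale — so interpolation error is subdominant and recovery
of planted totals can be judged against a 10% yardstick. The rim
coverage matters: with radars stopping short of the rim, the outflow
column is extrapolated and spurious take-off appears exactly where the
wave exits.

## Problem sizes used by the tests

Unit fixtures run on 3–6-cell-wide grids; scenario-level tests share one
memoised forward simulation of the default scenario; the ensemble
contracts use 200 realizations on a 5 × 5 grid; the end-to-end
benchmark uses the dense network with a kriging-estimate pass
(zero noise) and a 50-realization ensemble pass (standard noise). These
sizes are the package's chosen desk scale: large enough that every code
path (masking, boundary tags, multi-night labelling, ensembles) is
exercised, small enough to iterate on.

## Known limitations

* **Positive-part inflation.** Nightly take-off totals sum max(W, 0)
  over cells and steps. Any zero-mean noise in the reconstructed W —
  and conditional-simulation texture is exactly that — inflates such
  sums systematically, while net quantities (nightly ground change,
  boundary totals) are nearly unbiased. With sparse networks the effect
  is large; it shrinks, but does not vanish, on the dense benchmark.
  Consequently the ensemble Q5–Q95 of take-off totals sits above the
  planted truth under noise, and even for the nearly unbiased ground
  change the envelope can narrowly miss on heavy-departure nights: the
  stationary covariance treats the deterministic pulse as stochastic
  texture, so the ensemble spread does not fully represent the
  estimator's own smoothing bias at the rim. The acceptance checks
  compute and report both coverages rather than hide the effect.
* **Stationarity.** A single separable covariance for a field that is
  "blob against near-zero background" overstates local variance between
  radars; a nonstationary mean (the full reference methodology this
  package deliberately simplifies) would narrow it.
* **FTCS forward runs** are only weakly stable; the generator guards
  (Courant, clipping budget) are part of the scenario contract, not of
  the inversion, which is algebraic.
* **Below-beam and topographic corrections** are a two-strategy switch,
  not a reconstruction of any specific operational product.
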