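---
title: "Resilience of phenotypic memory in a bistable toggle switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience of phenotypic memory in a bistable toggle switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchres)
```

## The scientific problem

Many microbial gene circuits store a phenotypic state long after the
stimulus that induced it is gone. A canonical device is the two-gene
toggle switch: LacI and TetR each repress the other's promoter, so the
circuit has two mutually exclusive high-expression states, read out by
GFP (tracking the TetR side) and RFP (tracking the LacI side). Small
molecules tune the effective repression strengths — modelled here as the
dissociation constants `k_lac` and `k_tet` — and over an intermediate
range of those knobs the circuit is bistable: the state a cell occupies
depends on its history.

Bistability ends at a saddle-node bifurcation, where one stable state
collides with the saddle between them and vanishes. Near that critical
transition the surviving state's basin of attraction is shallow, so a
*transient* environmental perturbation — one that would be harmlessly
absorbed far from the transition — can push cells across the basin
boundary (the separatrix) so that they relax into the opposite state
after conditions are restored. `switchres` implements the full analysis
arc for studying this loss of resilience: the deterministic circuit
model, an exact stochastic simulator with perturb-and-recover protocols,
flow-cytometry style population analysis, inference of the separatrix
from two-channel fluorescence distributions, an empirical bifurcation
mapping, early-warning indicator statistics, and a ground-truthed
synthetic data generator that makes every stage testable end to end.

## The deterministic model

The rate equations for the two repressor concentrations are

$$\dot{L} = \frac{P_{Tet}}{1 + (T/K_{Tet})^n} - \gamma L, \qquad
  \dot{T} = \frac{P_{Lac}}{1 + (L/K_{Lac})^n} - \gamma T,$$

with promoter strengths $P$, dissociation constants $K$, Hill exponent
$n = 2$ (cooperative repressor binding; parameterised but not varied),
and a shared dilution rate $\gamma$ — the proteins are stable, so
degradation is dilution by cell division and one generation is
$\ln 2/\gamma$ time units. The reference parameter set is the
equal-promoter one, $P = 50$, $K = 15$, $\gamma = 0.5$; an asymmetric
set $P_{Lac} = 30$, $P_{Tet} = 35$ probes how the basin geometry changes
when the promoters differ.

```{r fixed-points}
p <- model_params()
find_fixed_points(p)
```

Fixed points are found by substituting the $\dot T = 0$ nullcline into
the $\dot L = 0$ one, which reduces the steady state to a single scalar
equation in $L$ whose roots provably lie in $(0, P_{Tet}/\gamma]$. Sign
changes are bracketed on a 2000-point log-spaced grid and refined by
bisection — derivative-free and exhaustive on the containment box.
Stability comes from the analytic Jacobian; a fixed point is rejected
("marginal") when an eigenvalue's real part is within `1e-10` of zero,
which protects classification exactly at a saddle-node.

### Basins, boundary lines and numerical choices

`basin_map()` labels a grid of initial conditions (default 101×101,
log-spaced over $[10^{-2}, 1.2P/\gamma]$ per axis) by the attractor each
trajectory reaches. All grid nodes are advanced *together* by a
fixed-step RK4 scheme with step $0.1/\gamma$ — comfortably inside the
stability bound, since the largest local rate at the defaults is about
$2.7$ — and a node is released once it comes within $10^{-3} P/\gamma$
of an attractor. Nodes that run into the saddle instead (initial
conditions on the separatrix itself, e.g. the exact diagonal under
symmetric parameters) are labelled `NA` and counted separately; a node
that reaches nothing by $t = 200/\gamma$ is unresolved, and more than 1%
unresolved is an error. The vectorised integrator is cross-checked
against `deSolve::lsoda` in the test suite; `integrate_toggle()`
exposes `lsoda` directly for single trajectories.

One geometric point deserves emphasis because it shapes both the
boundary-line fit and the bifurcation mapping below. Between the two
attractors, the separatrix is very nearly straight — in *linear*
concentration coordinates its full-grid linear fit reaches
$R^2 \approx 0.995$ at the asymmetric parameter set, and under symmetric
parameters it is exactly the diagonal (slope 1, intercept 0 in log-log
coordinates). Away from the attractors, however, the separatrix bends
toward horizontal/vertical asymptotes, so in log-log space its global
linearity degrades ($R^2 \approx 0.73$ over the default grid at
$P_{Lac}=30, P_{Tet}=35$). The log-space line is therefore fitted, and
should be read, as a statement about the inter-attractor region —
`extract_boundary(map, trim_to_attractors = TRUE)` restricts the points
accordingly ($R^2 \approx 0.99$ there). That is also the region where
perturbed cells actually sit.

```{r boundary}
bm <- basin_map(p)
fit_boundary_line(extract_boundary(bm))
```

`bifurcation_scan()` sweeps one parameter (the model proxy for an
inducer concentration), recomputing fixed points per value; the
bistable window is the contiguous run with three fixed points, and the
saddle–stable gap closing at the window edges is the saddle-node
signature. At the defaults the `k_tet` window is roughly $[7.2, 23.1]$.

## The stochastic model and perturbation protocols

The stochastic counterpart has four reactions — Hill-repressed
production and first-order degradation of each repressor — simulated
exactly (exponential waiting times, propensity-weighted reaction
choice) by a compiled inner loop driven by R's RNG stream, so
`set.seed()` makes every run reproducible. Two deliberate choices:

* **System size 1.** Concentrations are identified with molecule counts
  (so the states sit near 98 and 2 molecules). This makes
  perturbation-induced basin escapes observable at realistic ensemble
  sizes; the volume-scaling test multiplies $P$, $K$ and the initial
  counts by $\Omega = 10$ and verifies that within-basin fluctuations
  shrink like $\sqrt{\Omega}$ toward the deterministic limit.
* **Hill functions on integer counts.** The propensities evaluate the
  repression function at the current counts directly, with no
  half-molecule offsets — the simplest faithful discretisation of the
  rate equations.

`apply_protocol()` runs the three-phase experiment: an ensemble
(default 100 cells) starts at the high-LacI fixed point rounded to
integers, equilibrates for 10 generations, has one parameter switched
to a perturbed value for a chosen duration, then recovers at baseline
for 10 generations (several relaxation times at the defaults; the
recovery length is a design choice, as is perturbing `k_lac` — raising
it destabilises the high-LacI state, lowering it stabilises it; both
the field and value are configurable). A cell counts as `high_lac` when
`n_lacI > n_tetR`, ties going to `high_tet` — a documented arbitrary
rule for a measure-zero case.

```{r sweep}
sw <- duration_sweep(p, perturbation_protocol(
  n_cells = 40, perturbed_field = "k_lac", perturbed_value = 100,
  seed = 7), c(0.2, 1, 2, 5, 20))
sw[, 1:3]
```

The sweep reproduces the two qualitative laws of transient
perturbations: the switched fraction grows with both duration and
intensity, with the minimum effective duration of a severe perturbation
set by roughly one cell-division time; and perturbations that deepen
the occupied basin (e.g. `k_lac` lowered to 1) induce essentially no
switching at any duration. The same holds when the perturbation goes
through a promoter strength instead.

## Cytometry conventions

Event tables carry forward/side scatter and two fluorescence channels
per cell, with strictly positive values enforced on load (non-positive
rows dropped and counted). Three conventions matter:

* **Narrow scatter gates.** A per-cell size factor multiplies all
  channels (and drives the scatter), so fluorescence variability mixes
  expression noise with size noise. Gating to ~200 of ~10,000 events in
  a tight (log FSC, log SSC) window largely removes the size component.
  Gates here are reproducible objects, not hand-drawn polygons: the
  default retains exactly `target_count` events nearest the 2-D scatter
  mode ("densest", deterministic) or a random centre (seeded), and a
  quantile-window variant is available. Statistics get uncertainty from
  `r = 3` randomly placed gates (mean ± SE across gates), mirroring the
  three-gating convention; raise `r` for tighter intervals.
* **Switched-cell classification.** A cell is switched when its
  log10(GFP/RFP) crosses the midpoint between the two reference-state
  centroids' log-ratios, relative to its history. The rule is
  ratio-based (invariant to common channel rescaling, matching the
  slope-1 separatrix geometry) but deliberately independent of the
  fitted threshold $\alpha$, so measured fractions never feed the fit
  circularly.
* **Kinetics.** Survival curves over a time course are summarised by a
  convexity statistic — the mean second divided difference of
  log-survival — which is 0 for first-order switching and positive for
  mixtures of fast and slow switchers (non-exponential kinetics).

## Separatrix inference and the bifurcation mapping

The core inference assumes cells switch when their GFP/RFP ratio falls
below a threshold $\alpha$ — a slope-1 line in log-log fluorescence
space. For each perturbation, the end-of-perturbation distribution
predicts a switched fraction as a function of $\alpha$; the measured
fraction comes from the end-of-recovery table via the midpoint
classifier. `fit_alpha()` minimises the mean squared deviation between
predicted and measured fractions across all perturbations (eight by
default). Because the objective is piecewise constant with breakpoints
at the pooled observed ratios, the *exact* global minimum is found by
enumerating one candidate per piece; the returned $\alpha$ is the
geometric midpoint of the minimising plateau (unbiased under channel
log-scaling), with half-decade sentinels beyond the extremes.
Uncertainty is reported as mean ± SD of $\log_{10}\alpha$ over fits
repeated on randomly placed gates (`r = 3` by default, the three-gating
convention; the SD across gatings is our reading of the shaded
μ ± σ band, which the source convention leaves ambiguous).

The empirical bifurcation diagram takes, per knob value, the centroids
of the unswitched subpopulations as the stable branches and estimates
the unstable point as the intersection of the fitted separatrix with
the straight log-space line through the two centroids.

### A known limitation, quantified

On mechanistically generated data (below) the fitted $\alpha$ tracks
the true saddle *ratio* well (within ~0.1 decades), and the estimated
unstable branch moves toward the high-GFP branch exactly as the
generating model's saddle does. But the unstable point's *location* is
systematically biased: the saddle does not lie on the straight log-space
line connecting the stable states. Already in count space, that line
crosses the diagonal at the geometric mean of 97.7 and 2.3 — about 15 —
while the saddle sits at 25.6. Across a `k_tet` sweep the estimated
unstable log-GFP falls 0.19–0.33 decades below the true saddle's,
roughly 10–15 times the Monte-Carlo SE of the estimate. The
centroid-line construction is therefore a good *relative* indicator of
basin shrinkage and a poor absolute locator of the saddle; the test
suite asserts the former and deliberately documents the latter as a
failing expectation rather than hiding it.

## The synthetic data generator

Two modes, both emitting ground-truth labels and full generating
parameters:

* **Phenomenological.** Fluorescence is a two-state lognormal mixture on
  the log10 scale (state log-means 2.8/0.8 with SD 0.15 per channel,
  two decades of separation), times a common size factor (log10-SD 0.1)
  shared with the scatter channels, plus an autofluorescence floor of
  1 a.u.; unperturbed controls carry 0.5% background switching; tables
  default to 10,000 events. Perturbations displace the history cloud
  toward the other state in log-ratio by a graded amount (0.8–2.8
  decades across the eight named perturbations) and broaden the spread
  (×2.4), producing the intermediate, threshold-straddling
  distributions seen at the end of a perturbation; recovery redraws
  each cell from the state dictated by the ground-truth threshold
  (optionally flipped with a small noise probability). The displacement
  magnitudes are internal-consistency placeholders — what each real
  stress does to the distribution is an open question — graded so the
  eight measured fractions span ~0 to ~0.95 and pin the threshold well.
* **Mechanistic.** Stochastic ensembles of the circuit itself, with the
  knob identified with `k_tet` and perturbations as transient `k_tet`
  multipliers for 2 generations; counts map to fluorescence as
  GFP $= b_g \cdot n_{TetR} \cdot$ size $\cdot$ noise + floor (and RFP
  from $n_{LacI}$), with brightness 30 a.u./molecule and log10
  measurement noise 0.05. The GFP↔TetR pairing is forced by the history
  design of the emulated experiments: disabling LacI puts cells in the
  high-GFP state, and high knob values collapse everything to high-RFP.
  Mechanistic tables default to 2000 cells — enough for centroids and
  threshold fits at a few seconds per knob on one core.

What the generator does *not* emulate: instrument-specific noise
(spillover, laser drift), growth and dilution bookkeeping between
timepoints, cell-division partitioning noise, or any biochemical model
of the stresses. Tests passing on this generator therefore certify the
*analysis operations* — gating, classification, threshold fitting,
indicator statistics — under the stated statistical structure, not the
biology of any particular perturbation.

## Early-warning indicators

Per knob value, the mean and the coefficients of variation (linear and
log10, sample SD over mean) of the history channel are computed on
gated, unswitched cells only. Error conventions follow the underlying
measurement: the mean's SE comes from three random gate placements
(gate position moves the size-correlated mean, which resampling cells
within one gate cannot see), the CVs' SEs from 200 bootstrap
resamplings. Trends across the knob are assessed by the least-squares
slope with a parametric bootstrap that perturbs each knob's point
estimate by its total SE — for the CVs, the bootstrap SE combined in
quadrature with the gate-placement SE; the trend is significant when
the 95% interval excludes zero. Calibrated this way, flat generating
conditions produce false-positive trend calls at or below the nominal
rate, while injected variance inflation (state log-SDs scaled up to
2× across the sweep) is reliably flagged. This mirrors the headline
null result the package is built to probe: indicators based on local
stability can stay flat even close to the transition.

## Pipeline and reproducibility

`validate_config()` reads a YAML run configuration, applies defaults
and reports all invariant violations at once; `run_all()` executes the
full arc — stochastic duration sweep, synthetic bundle, gated switched
fractions, per-knob separatrix fits, bifurcation table, indicator
series — writing CSVs and a run log. One master seed fans out to every
stage through a deterministic child-seed scheme, so a config plus a
seed yields byte-identical outputs, and any stage can be re-run in
isolation with its own seed.

## Problem sizes used by the checks

The shipped tests and the acceptance script run, per invocation: 101×101
basin maps; duration sweeps of 100-cell ensembles over
{0.2, …, 20} generations; separatrix fits on 8 perturbations × 2000
events across several seeds; a mechanistic `k_tet` sweep at 500 cells
per table over four knob values approaching the saddle-node edge
(~23.1); indicator series over four knob values at 2000 events with 200
bootstrap resamples; and a 10,000-snapshot birth–death stationary
check. These sizes were chosen as comfortable single-core desk-scale
runs that keep every Monte-Carlo tolerance meaningful.
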