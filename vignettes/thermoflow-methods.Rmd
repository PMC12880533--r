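---
title: "Modelling a multilayer thermal-gradient blood-flow sensor"
author: "thermoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a multilayer thermal-gradient blood-flow sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A calorimetric flow sensor infers flow from the asymmetric advection of
heat: a small disk heater sits on the skin over a vessel, and thermistors
placed upstream and downstream of it read how strongly the thermal plume
is skewed in the flow direction. For microfluidics this works directly,
because the channel depth is known. Over skin it does not: the
temperature asymmetry depends on both the flow rate `f` and the vessel
depth `d`, and a single sensing layer cannot separate the two. The
device modelled here resolves the ambiguity with **two** thermistor
layers — one flush with the surface, one elevated 1.5 mm above it on an
air gap — so that the vertical decay of the thermal field adds the
depth information that a single layer lacks. Six channels result:
upstream, downstream and reference thermistors in each layer, the
references sitting at the same distance from the heater but
perpendicular to the vessel, outside the flow path.

`thermoflow` is a desk-scale digital twin of this system: a forward heat
transport solver for the benchtop phantom, a model of the
thermistor/bridge/filter signal chain, a synthetic-data generator that
mirrors the benchtop protocol, a neural regressor that inverts the six
channels into `(f, d)` simultaneously, and a two-branch model that fuses
the recovered flow sequence with a photoplethysmography (PPG) waveform
for continuous blood-pressure estimation.

## Forward model

The phantom is a PDMS block with a cylindrical water channel along `x`
(diameter 2.5 mm by default), the top of the channel a depth `d` below
the surface. A copper disk actuator (diameter 3.5 mm, 56.7 mW, i.e.
5.89 mW/mm^2) sits on the surface directly above the channel axis; an
air gap occupies the region above the surface, hosting the elevated
sensing layer at `H` = 1.5 mm.

Steady heat transport solves conduction in all materials plus
advection in the channel:

* finite volumes on a uniform Cartesian grid, harmonic-mean face
  conductivities (exact for layered media), first-order upwind advection
  with a prescribed velocity profile — plug by default, a developed
  parabolic profile as an option (velocity is prescribed, not solved;
  momentum is out of scope);
* boundary conditions follow the bench: bottom surface fixed at 25 C,
  insulated lateral faces, convective top with `h` = 15 W/(m^2 K) to the
  ambient, water entering at 25 C, zero-diffusive-flux advective
  outflow;
* material properties: PDMS (0.16 W/m K, 1460 J/kg K), water
  (0.6 W/m K, 4184 J/kg K), copper (400 W/m K, 385 J/kg K); densities
  965 / 1000 / 8960 kg/m^3; the air gap is modelled as a conducting
  medium (0.026 W/m K) — no convection inside the 1.5 mm gap.

The linear system is solved by ILU(0)-preconditioned BiCGSTAB (written
in C++ for this package; relative residual 1e-8). Transient runs use
implicit Euler with the matrix reused across steps of constant flow.
Verification is built into the test suite: a closed-form two-layer slab
solution with a Robin top face is reproduced to well under 0.5%, a
surface-integral energy balance closes to machine accuracy, the
zero-flow field is up/downstream symmetric, and heating never drives any
cell below the coldest boundary (maximum principle).

### Numerical choices

* **Grid spacing 0.5 mm.** The channel spans 5 cells per diameter and
  the majority-coverage voxelization (a cell is fluid when at least half
  of it lies inside the true cylinder, judged on an 8 x 8 subgrid) keeps
  the cross-section area within 10% of `pi r^2`. One steady solve on the
  default 30 x 20 x 10 mm block (plus air gap) has about 60k unknowns
  and takes a couple of seconds, which is what makes the 30-condition
  protocol, the ambient study and the sweeps routinely runnable; grid
  convergence (halving the spacing changes probe temperatures by about
  1%, and softens rather than reshapes the flow response) is checked
  separately.
* **Reduced block.** The full 8 x 9 cm bench phantom is thermally
  far-field for a 3.5 mm heater; the model truncates it to
  30 x 20 x 10 mm with insulated faces. Unit tests run on an even
  smaller 16 x 12 x 8 mm block — same physics, faster solves.
* **Vessel depth convention**: `d` is measured from the surface to the
  *top* of the channel, matching how phantom layers were stacked on the
  bench; it is configurable through `phantom_geometry()`.
* **Tubing wall ignored by default** (the FEA material list has only
  PDMS/water/copper); a wall with its own material is available for the
  sensitivity sweeps. Vessel wall *stiffness* is accepted as a sweep
  parameter but has no coupling into the heat equations — a pure
  heat-transfer model — so its sweep is exactly flat, which is itself a
  specification of the expected behaviour.

## Signal chain

Probe temperatures pass through the measurement electronics model:
10 kOhm NTC thermistors (beta model, B = 3380 K — a typical value for
this part family; the data sheet beta is configurable), Wheatstone
half-bridges against the same-layer reference thermistor with a
differential amplifier (3.3 V supply, 10 kOhm fixed arms, gain 100 —
plausible defaults for the named parts, none of which are critical
because the inversion network standardizes its inputs), an exponential
moving average with smoothing coefficient 0.05 at 20 Hz, and decimation
to 1 Hz by non-overlapping 20-sample means. The "moving average filter
with a smoothing coefficient" is implemented as the exponential
recursion `y_t = 0.05 x_t + 0.95 y_{t-1}`: a windowed mean has no single
smoothing coefficient, while the EMA is exactly parameterized by one.

Three feature modes feed the regressor:

* `temperature` (default): the six filtered temperatures;
* `compensated`: the four per-layer differences (up - ref, dn - ref),
  i.e. digital reference compensation after per-thermistor
  linearization. Because the forward problem is linear in temperature, a
  chamber-wide ambient shift moves every probe equally and these
  features are exactly invariant;
* `bridge`: the four analog bridge voltages. These reject a common-mode
  offset but keep the NTC nonlinearity, so their gain droops a few
  percent per kelvin of ambient shift — the reason the ambient
  robustness study uses the compensated mode.

## Synthetic benchtop protocol

The generator reproduces the bench protocol: vessel depths
{1, 1.5, 2} mm crossed with flows 1..10 mm/s (30 conditions), 50
measurements per condition (n = 1500; the expanded variant uses 300 for
n = 9000). One steady solve per condition is cached; replicates are
fresh draws of i.i.d. Gaussian sensor noise pushed through the full
filter chain — the bench's replicates are repeated physical
measurements, and re-noising a cached solve is the desk-scale
equivalent.

**Noise calibration.** The replicate noise magnitude is not reported
for the bench, so it is a declared generator choice. The default SD is
0.0075 C on each 20 Hz probe sample, set so that the noise-limited
flow-recovery error at the least sensitive end of the measurement range
(f near 10 mm/s, where the downstream differential changes by only
~0.05 C per mm/s) is of the order of the +/- 0.12 mm/s bench margin;
after the 0.05-EMA and the 1 s average it corresponds to ~2 mK on a
feature, a plausible noise floor for a 10 kOhm bridge at 20 Hz.

Cross-validation is grouped *by condition*: the 30 `(d, f)` pairs are
partitioned into five folds of six, so all 50 replicates of a condition
stand or fall together — 1200 training and 300 test rows per fold — and
the evaluator hard-errors if a condition ever appears on both sides.

## Inversion network

The regressor is a multilayer perceptron, six inputs to two outputs
(flow mm/s, depth mm), written in plain R matrix algebra so a fixed
seed reproduces training bit-for-bit. Architecture: linear layers with
batch normalization and ReLU, 10% dropout, hidden widths 128-128-64.
Inputs and targets are standardized with statistics from the training
fold only; the loss is unweighted MSE over both standardized outputs;
the optimizer is Adam (initial rate 2e-3, stepped down 10x after 60%
and again after 85% of 300 epochs, minibatch 64). Two details matter
for accuracy at this data scale and were chosen deliberately:

* **Dropout placement.** The published architecture regularizes with
  10% dropout but does not say where. Applied after *every* hidden
  layer of a network this small, dropout noise caps the achievable
  training fit near 0.2 mm/s. Applied once, on the last hidden
  activation, the deterministic evaluation network is *exactly* the
  dropout-ensemble mean (the output layer is linear), and the fit
  reaches the interpolation regime. The package defaults to last-layer
  dropout; `regressor_spec(dropout_layers = "all")` restores the
  everywhere variant.
* **Batch-norm re-estimation.** After training, the batch-norm running
  statistics are recomputed exactly over the full training set, so
  evaluation-mode normalization matches the data actually trained on
  rather than a momentum average over shuffled minibatches.

## What the twin does and does not reproduce

All structural properties of the measurement principle carry over and
are asserted by tests: the downstream skew grows with flow and stays
strictly positive over 1-10 mm/s; the six-channel response separates
all 30 conditions by more than the noise SD while the bottom-layer
differential alone collides across depths (the single-layer ambiguity
that motivates the second layer); dual-layer features recover depth
strictly better than bottom-only features; compensated features are
ambient-invariant while raw ones are not; step changes in flow are
tracked with settling times that grow with vessel depth.

The *quantitative* error bounds of the bench do not all transfer. In
this twin the thermal response saturates roughly hyperbolically in `f`
(the advection-dominated regime at cell Peclet numbers of 3-35), so in
feature space the f = 1 mm/s conditions sit far outside the convex hull
of the remaining grid and the f = 10 conditions crowd together. Under
condition-grouped cross-validation — where entire conditions are held
out — predicting a held-out corner condition is extrapolation, and its
error (several tenths of mm/s) dominates the pooled 95th percentile.
This is a property of the inverse problem the simulator generates, not
of the regressor: a radial-basis interpolation oracle run directly on
the noiseless condition-mean features shows the same corner failures.
The bench device evidently has a more benign response curve; matching
its mesh-level numbers is explicitly out of scope. The depth output is
much better conditioned (three well-separated depths), and its pooled
95% error does meet the bench margin. Consequences for the headline
checks: the pooled 95% flow error and the worst per-flow depth RMSE at
f = 1 sit above the bench's +/- 0.12 mm/s and 0.07 mm bounds, and the
ambient study's worst single measurement (a max over 150 draws, at the
high-flow end) lands near 0.2 mm/s; all are reported as computed.

## Blood-pressure fusion demonstration

The cardio generator writes records with an aligned 1 Hz flow sequence,
128 Hz PPG waveform and reference SP/DP. Pressures follow baseline
120/80 mmHg with a slow autonomic drift plus a Valsalva maneuver
(onset 200 s, duration 140 s) whose four phases — strain-onset
elevation, compensatory decline, release drop, overshoot — have
configurable offsets, (+15, -20, -15, +10) mmHg by default. Flow
couples to mean arterial pressure (0.05 mm/s per mmHg), so it declines
during the maneuver; the PPG pulse (two Gaussians per beat: systolic
peak plus dicrotic hump) has its amplitude modulated by pulse pressure.
The drift is therefore visible in the flow channel but not in the PPG
amplitude — that is the independent information the fusion can exploit,
and setting the coupling gain to zero removes it, which the tests use
to show the fusion gains vanish when they should.

The estimator follows the two-branch architecture: an LSTM over the
10 s flow window and a 1-D convolution + ReLU + pooling bank over the
10 s PPG window, concatenated into a fully connected head that outputs
SP and DP at 1 Hz. The branch weights are fixed random projections
drawn from the seed and only the head is trained, by ridge regression —
an echo-state-style design choice that keeps training closed-form,
deterministic and fast while preserving the branch structure and every
comparative property of interest (fused vs PPG-only, record-level
splits, Bland-Altman agreement). The PPG-only baseline simply omits the
flow branch. Evaluation always splits by record, never within one.

## Problem sizes and runtimes

Chosen so the full default protocol runs comfortably on one CPU: the
default steady grid is ~60k unknowns (~2 s per solve, 30 solves for the
condition grid), cross-validation trains five networks of ~30k
parameters (~3 min total), the ambient study reuses the cached training
solves plus 15 elevated-ambient solves, and the unit-test suite runs on
a reduced 16 x 12 x 8 mm block. The acceptance script executes the
whole chain — dataset, grouped CV, ambient study, stiffness sweep — from
scratch in roughly a quarter of an hour.

## Known limitations

* Velocity is prescribed (plug or parabolic); no momentum solution, no
  pulsatility, no Taylor dispersion.
* The acrylic supports and the fPCB are not in the thermal model; the
  air gap is purely conductive.
* The response-curve mismatch discussed above: corner-condition
  extrapolation errors exceed the bench margins under grouped CV.
* The cardio generator is a minimal controllable morphology, not a
  physiological simulator: no respiratory modulation of PPG, no motion
  artifacts, no baroreflex dynamics beyond the scripted four phases.
* Replicate noise is i.i.d. Gaussian; bench noise likely has drift and
  1/f components that the reference compensation would partly remove.
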