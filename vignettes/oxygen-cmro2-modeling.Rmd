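---
title: "Modeling tissue oxygen transport and CMRO2 during spreading depolarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tissue oxygen transport and CMRO2 during spreading depolarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyslice)
```

## The problem

In an interface-chamber brain slice, oxygen enters through the surface
(humidified carbogen above, perfusate below; the gas phase dominates the
supply), diffuses into the tissue and is consumed by mitochondrial
respiration. At steady state the partial tissue oxygen pressure
$p(x)$ therefore falls monotonically from the surface toward a minimum —
the "core" — and the *shape* of that depth profile encodes the volumetric
oxygen consumption rate, the cerebral metabolic rate of oxygen (CMRO2).
During spreading depolarization (SD), the near-total breakdown of ion
gradients forces the Na$^+$/K$^+$-ATPase to work at its limit, consumption
surges, and the depth profile collapses within seconds.

`oxyslice` implements the forward physics, the inverse estimation, the
trace-feature extraction and the statistics needed to run this analysis end
to end on synthetic data with known ground truth.

## The slice model

The planar forward model is the steady-state reaction–diffusion equation

$$D \frac{d^2 p}{dx^2} = M \frac{p}{p + K_m},$$

with $p(0)$ fixed at the surface supply value (Dirichlet) and $dp/dx = 0$ at
the depth of the pO2 minimum (the tissue below the minimum is supplied from
the perfusate side; no net flux crosses the minimum). Oxygen consumption
saturates with Michaelis–Menten kinetics. The constants, with defaults:

| parameter | symbol | default | units | role |
|---|---|---|---|---|
| diffusion constant | $D$ | 1600 | µm²/s | Fick diffusion in tissue |
| Michaelis constant | $K_m$ | 3 | mmHg | half-saturation of respiration |
| layer thickness | $h$ | 1 | µm | discretization grid |
| consumption rate | $M$ | fitted | mmHg/s | CMRO2, assumed depth-homogeneous |

CMRO2 is carried throughout in partial-pressure units (mmHg/s); no
conversion to molar units is attempted, so no solubility coefficient ever
enters.

Assuming a *homogeneous* $M$ across depth is an abstraction — dendrites,
somata and glia consume differently — but it is the assumption under which
the single-parameter inverse problem is well posed, and homogeneous-fit
residuals on measured-like profiles are small.

### Discretization and solver

Both geometries use a node-centered finite-volume scheme in flux form:
interior balances equate face fluxes $D\,A_{i\pm1/2}(p_{i\pm1}-p_i)/h$
with consumption integrated over the control volume, and the closed
boundary node owns a half cell. Written this way the discrete solution
conserves oxygen *exactly*: in the cylinder, the influx through the vessel
wall equals the summed shell consumption to machine precision
(`oxygen_flux_balance()`), which matters because the hypoxia-boundary scan
compares solutions across many geometries.

The Michaelis–Menten nonlinearity is solved by quasi-linearized Picard
iteration: the reaction term is frozen as $c(p^{(k)})\,p$ with
$c = M/(p^{(k)}+K_m)$ and the resulting tridiagonal system solved exactly
(Thomas algorithm, in C++). That linear system is an M-matrix with a
non-negative source, so *every iterate is strictly positive* — no
clamping, no projected steps, and no way for the iteration to stall on a
spurious fixed point. (A damped-Newton variant with a non-negativity clamp
was tried first and abandoned: near fully hypoxic cores the clamp could
freeze the update norm while the residual was still large, which produced
occasional wrong "solutions" and broke the unimodality of the fit
objective.) Convergence is declared when the largest node update falls
below $10^{-6}$ mmHg *and* the nonlinear flux residual is at round-off
scale; the iteration cap is $10^4$, after which the solver aborts with the
last residual rather than returning silently.

At zero consumption both solvers return the boundary value exactly (the
linear solve of the Laplace system is exact). Halving the grid changes no
node by more than 0.1 mmHg at the default parameters, and in the
effectively zero-order limit ($K_m \to 0$, $p \gg K_m$) the planar solution
matches $p_s - Mx(2L-x)/2D$ and the cylindrical solution the Krogh–Erlang
form to well under 0.5 % of the boundary value.

## Inverse estimation of CMRO2

`fit_cmro2()` treats $M$ as the single adjustable parameter and minimizes
the unweighted sum of squared differences between the forward solution and
the measured pO2 at the recorded depths (no depth weighting: the electrodes
are identical and nothing justifies one). The minimization is Brent's
method on $[0, 500]$ mmHg/s with tolerance $10^{-3}$; for noiseless forward
profiles the objective is unimodal on that interval (verified by sweep in
the tests), so a scalar line search is sufficient and deterministic. An
estimate within $10\,\times$ tolerance of either bound is flagged as a
boundary hit, not silently returned as converged.

Two acquisition designs are supported, and they differ in where the
Dirichlet value comes from:

* **multi-step** (one electrode stepped every 20 µm): the shallowest
  measurement is the boundary value, anchored at its own depth, and is
  excluded from the residuals — the model is conditioned on it;
* **three-point** (fixed electrodes at e.g. 40/100/160 µm): the supply pO2
  must be supplied from configuration. The recordings the package emulates
  do not come with a universal supply value — it depends on chamber and
  flow — so it is deliberately a *required* input rather than a default
  hidden in the code. The synthetic-data configuration uses 400 mmHg, a
  mid-range value for interface chambers gassed with 95 % O2 and, not
  coincidentally, a value large enough that the baseline profile keeps a
  positive core minimum at 160 µm depth ($M L^2/2D \approx 275$ mmHg of
  zero-order drop at baseline consumption).

### Time-resolved fits

SD is too fast for a stepped electrode, hence the three fixed electrodes.
`fit_cmro2_timeseries()` fits every time sample independently under a
quasi-steady-state assumption, after a centered 1-s moving average on the
pO2 channels. The diffusional equilibration time of the slice,
$L^2/D \approx 16$ s for a 160-µm domain, bounds how fast true CMRO2
changes can be tracked; this lag is documented, not deconvolved — the SD
consumption transient evolves over minutes, an order of magnitude slower.
The core depth is held at the deepest electrode position for the whole
episode even though the true pO2 minimum migrates upward during SD; the
deepest electrode is the only observable anchor for it.

The baseline is the median fitted CMRO2 over a configurable pre-onset
window, and `excess_cmro2_auc()` integrates
$\max(\widehat{M}(t) - \text{baseline},\, 0)$ by the trapezoidal rule over
the first 5 min after onset (negative excursions are clipped: the quantity
of interest is surplus consumption, and clipping keeps the AUC linear in a
uniform scaling of the excess).

## The perivascular (Krogh) model

To ask what the fitted consumption rates would mean for tissue supplied by
capillaries rather than a gassed surface, the cylindrical model solves

$$\frac{D}{r}\frac{d}{dr}\!\left(r\frac{dp}{dr}\right) = M\frac{p}{p+K_m}$$

between the vessel wall (held at capillary pO2; the vessel compartment
carries no intravascular gradient) and a closed outer radius — the classic
Krogh cylinder, with all radii measured from the axis. `oxygenation_map()`
scans capillary pO2 over 20–55 mmHg (the range reported for rodent cortical
capillaries) and outer radii over 10–35 µm (reported perivascular diffusion
distances; a 40-µm intercapillary distance corresponds to 20-µm cylinders),
and `hypoxia_boundary_radius()` reports, per capillary pO2, the largest
scanned radius whose *edge* pO2 — the field minimum — strictly exceeds the
~8 mmHg threshold below which oxidative metabolism fails. The boundary is
reported on the scan grid (integer µm, matching the shell discretization)
without sub-grid interpolation, and the strict `>` follows the convention
that a territory counts as supplied only above the threshold. Scans that
never cross the threshold return explicit sentinels (`Inf` "beyond scan
range", `-Inf` "below scan range") rather than fabricated radii. The maps
store raw solver output without clipping.

One geometric constant is genuinely unreported in the experimental
literature this emulates: the capillary lumen radius. It matters — the
boundary radius at capillary pO2 20 mmHg and baseline consumption moves
from 26 µm ($r_c = 2$) through 27 µm ($r_c = 2.5$) to 29 µm ($r_c = 3$).
The package default is **2.5 µm**, a standard rat cortical capillary
(~5 µm diameter) and the value at which the model reproduces the 27-µm
boundary; it is a configurable argument everywhere and is recorded in every
map output. When $(R - r_c)$ is not a whole number of nominal shells the
annulus is divided into the nearest number of *uniform* shells spanning it
exactly (≈1 µm each); the grid-refinement tests show the residual
sensitivity of this choice is below 0.1 mmHg.

## SD trace features

`extract_sd_features()` computes the per-event descriptors:

* **DC shift**: amplitude is the baseline-to-trough magnitude; duration is
  the full width at half of the maximal negative amplitude, with sub-sample
  linear interpolation of both crossings. Half-maximum is the standard
  width convention for SD negative DC shifts; the fraction is configurable
  because acquisition conventions differ.
* **Potassium transient**: the electrode voltage is converted with the
  decade form of the Nernst relation,
  $[K^+]_o = 3\,\text{mM} \cdot 10^{\Delta v/s}$, where the slope $s$
  defaults to the ideal $\ln(10)RT/F \approx 61.3$ mV/decade at 36 °C but
  is configurable — real ion-sensitive electrodes are calibrated and run
  slightly sub-Nernstian. $\Delta[K^+]_o$ is peak minus pre-onset baseline;
  T1_50 and T2_50 are the times from the peak to decay to 50 % and 10 % of
  the rise (the "T2_50" name for the 10 % landmark is kept as the field
  reports it). If the trace ends before 10 % recovery, T2_50 is reported
  censored, never extrapolated.
* **Oxygenation**: per-channel pO2 minima over a 5-min post-onset window,
  and a hypoxia flag when the deepest (core) channel falls below the
  threshold.

Onset detection (first sustained excursion below baseline mean minus
$\max(5\sigma, 2\,\text{mV})$, held ≥ 2 s) is deliberately simple; SD DC
shifts are an order of magnitude larger than either bound, and events in
practice are also often marked manually — the onset can always be supplied
explicitly. Baselines are medians over the 30 s before onset, which makes
every feature invariant to constant DC offsets and uniform time shifts
(property-tested).

### Isoflurane dosing conversion

Vapor concentrations convert to aqueous concentration as
$\text{mM} = \frac{\%}{100}\cdot\frac{1000}{V_m}\cdot\lambda$ with
water/gas partition coefficient $\lambda = 0.5424$ at 37 °C. The molar
volume convention matters at the second decimal: $V_m = 22.711$ L/mol
(ideal gas at 0 °C, 100 kPa) gives 0.24 / 0.72 mM for 1 % / 3 %, the values
standardly reported; 22.414 L/mol (0 °C, 101.325 kPa) gives 0.24 / 0.73,
and the 37 °C molar volume gives 0.21 / 0.64. The default is 22.711,
chosen to match the reported pair; both constants are arguments.

## The synthetic-data generator

There are no public recordings for this preparation, so every estimation
and extraction stage is exercised against `generate_sd_episode()`, which is
a *phenomenological* generator: it reproduces the landmark statistics of
the recordings (it does not simulate membranes, ion fluxes or SD
propagation). Its defaults are the medians of the untreated condition:
baseline CMRO2 34.4 mmHg/s rising 2.7-fold, DC half-amplitude width 43 s,
potassium transient +22.6 mM with decay landmarks 20 s / 65 s. Three
modeled channels:

* **CMRO2 waveform**: baseline plus an excess kernel
  $(1-e^{-u/\tau_r})e^{-u/\tau_d}$ normalized to peak 1
  ($\tau_r = 10$ s, $\tau_d = 120$ s), so elevated consumption outlasts DC
  recovery — the oxygen signature recovers minutes after the electrical
  one.
* **DC**: a logistic-edged negative rectangle (edge constant 0.5 s) whose
  half-amplitude width equals the configured duration. The 15-mV amplitude
  default is an explicit placeholder — it is not a reported statistic, and
  no analysis in the package depends on its value.
* **Potassium decay**: a stretched-exponential $e^{-(t/\tau)^\beta}$ with
  $(\tau, \beta)$ in closed form through both landmarks
  (`solve_decay_landmarks()`). A two-exponential mixture — the classical
  description of potassium clearance — *cannot* hit the default landmark
  pair: mixtures of exponentials are log-convex, so with the 50 % landmark
  fixed at 20 s the plain exponential already maximizes decay at 65 s,
  reaching only 10.5 %. The Weibull family covers both compressed
  ($\beta > 1$, the untreated medians: $\beta = 1.02$) and heavy-tailed
  ($\beta < 1$, the deep-anesthesia medians 38.3 s / 235.7 s:
  $\beta = 0.66$) clearance with two parameters for two constraints.
* **pO2 channels** are quasi-steady forward solutions under the CMRO2
  waveform — exactly the inverse model's assumption, which is what makes
  noiseless round trips exact and is also the generator's main idealization:
  real channels lag by the diffusion time and carry drift, neither of which
  is modeled. Passing round-trip tests therefore validates the estimation
  machinery, not the quasi-steady assumption itself.

Noise is i.i.d. Gaussian per channel (defaults: 1 mmHg pO2, 0.2 mV DC and
K-electrode voltage — conservative placeholders; the emulated recordings
publish no noise magnitudes). Every generator is a pure function of
(parameters, seed), restores the global RNG state, and emits its ground
truth alongside the data; no analysis stage reads the ground truth.

`generate_paired_cohort()` emulates the repeated-measures design: slice
level lognormal multipliers on baseline CMRO2 (sdlog 0.2) and on the
potassium transient (sdlog 0.5) shared between the conditions of a slice —
the sdlogs are back-calculated from reported interquartile spreads
(e.g. $\ln(40.1/30.8)/(2 \times 0.674) \approx 0.20$) — plus independent
lognormal measurement noise (sdlog 0.15) per episode. Under a zero
treatment effect the within-slice differences are symmetric about zero,
which is what makes the type-I-error calibration of the signed-rank test
meaningful.

## Statistics

`wilcoxon_signed_rank()` drops zero differences (Wilcoxon's convention),
assigns average ranks to ties, and for $n \le 25$ computes the exact
two-sided p from the full null distribution of the positive-rank sum —
evaluated by convolution over the rank multiset, which is algebraically the
same as enumerating all $2^n$ sign assignments (the tests verify exact
equality against a literal enumeration oracle up to $n = 8$). Above 25 it
uses the normal approximation with tie-corrected variance and continuity
correction. The two-sided p doubles the smaller inclusive tail, capped
at 1. Whether a historical analysis used the exact or approximate form is
rarely stated, so both are available and the result is always labeled.

Bonferroni adjustment takes the number of *planned* comparisons as an
explicit argument (the shipped design compares each treatment against
control but never treatments with each other, so $m$ = number of
treatments), and summaries are median (25th, 75th percentile) with
type-7 (linear order-statistic interpolation) quantiles, recorded in the
output so results are reproducible across software.

## Problem sizes and what the tests show

The test-suite simulations use: 200 noisy replicates per truth level for
recovery (median bias < 2 %, RMSE < 8 % at σ = 1 mmHg with the three-point
design), 500–2000 null cohorts at n = 13 for type-I calibration
(rejection within 0.035–0.065 at α = 0.05; the exact test at n = 13 attains
≈ 0.048), the full 36 × 26 capillary-pO2 × radius grid for map
monotonicity, and episodes at 2–10 Hz over 120–420 s. These sizes make the
whole suite run in well under a minute while leaving the Monte-Carlo
standard errors comfortably inside the asserted bands.

Because the generator shares the forward model with the estimator, the
round-trip accuracies reported by the tests are upper bounds on what real
recordings would give; the realistic-data caveats are the quasi-steady lag,
electrode drift, and spatial inhomogeneity of consumption, none of which
the synthetic data contains.

## Known limitations

* Steady-state only: no transient diffusion, no 2-D/3-D vascular
  geometries, no hemoglobin; the Krogh maps are equilibrium statements.
* Homogeneous CMRO2 across depth, fixed $K_m$ and $D$ (never co-fitted).
* The quasi-steady time-resolved fit under-resolves changes faster than
  ~16 s.
* The hypoxia boundary depends on the assumed capillary radius (±1–2 µm
  per 0.5 µm of lumen radius); it is a model sensitivity, not a measured
  quantity.
* The generator is phenomenological; agreement with it validates the
  analysis code, not the biophysics.
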