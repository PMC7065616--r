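---
title: "Quantifying corneal viscoelasticity from air-puff OCT hysteresis loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corneal viscoelasticity from air-puff OCT hysteresis loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneapuff)
```

## The measurement and the model

A noncontact tonometer fires a millisecond-scale air pulse at the cornea
while a swept-source OCT beam, collinear with the air jet, records an
M-scan: a depth-versus-time image in which each column is one A-scan of the
corneal apex. A pressure sensor inside the air-puff chamber logs the
stimulus on the same clock. Segmenting the anterior corneal interface gives
the apex displacement trace $x(t)$ (inward positive, micrometers);
converting the sensor readings through a strain-gauge calibration gives the
force trace $F(t)$ (newtons). Plotting $F$ against $x$ over one
deformation-recovery cycle yields the *dynamic corneal hysteresis loop*:
because the cornea is viscoelastic, the unloading path falls below the
loading path and the enclosed area is the energy dissipated by viscous
losses.

The descriptor set extracted from each loop:

* **MAD** — maximum apex displacement (µm), the peak of $x(t)$.
* **CCT triplet** — central corneal thickness before the puff
  (`cct_bef`), at maximum displacement (`cct_max`) and after recovery
  (`cct_aft`), from the segmented posterior surface.
* **HA** — hysteresis area (J): the loop integral $\oint F\,dx$, equal to
  the loading-phase area minus the unloading-phase area when both phases
  are monotone in $x$.
* **HR** — hysteresis ratio (%): $100 \cdot \mathrm{HA} / \int_0^{\mathrm{MAD}}
  F_{\mathrm{loading}}\,dx$, the dissipated fraction of the loading energy.
* **S_sec** — secant slope (N/m) between the 10%-of-MAD point and the MAD
  point of the loading curve.
* **S_low, S_high** — least-squares slopes (N/m) of the first and last
  120 µm of the loading curve (starting at the 10%-of-MAD point and ending
  at MAD respectively). On the J-shaped loading curves of real corneas
  these separate the compliant extracellular-matrix regime from the stiffer
  collagen-stretching regime.

No public air-puff OCT M-scan data set accompanies this package, so every
stage is validated against a fully controlled synthetic pipeline built on a
**Kelvin–Voigt phantom**: a spring $k$ (N/m) in parallel with a dashpot $c$
(N·s/m) driven by the calibrated force pulse,

$$ c\,\dot x(t) + k\,x(t) = F(t), \qquad x(0) = 0 . $$

This is the simplest model that produces a hysteresis loop of the observed
kind; stiffening with intraocular pressure (IOP) is emulated by increasing
$k$, and a change of viscous character (e.g. through tissue dehydration) by
changing $c$. A massless element is deliberate: an inertial term would add
a second parameter the experiments cannot separate, and the apex dynamics
of interest are overdamped at the stimulus time scale.

## The numerical core

**Integrator.** `kv_response()` advances the ODE with an exact per-step
exponential update that treats $F$ as piecewise-linear between samples. The
update is the closed-form solution on each interval, so the scheme is
unconditionally stable, introduces no tunable tolerance, and reproduces
step and sinusoidal closed forms to better than $10^{-6}$ relative (the
test suite also cross-checks it against an independent stiff ODE solver).
For $c = 0$ the algebraic elastic solution $x = F/k$ is returned directly.

**Loop area.** `hysteresis_area()` evaluates $\oint F\,dx$ as a
time-parameterized trapezoidal (shoelace) line integral, closing the loop
from the last sample back to the first. A time parameterization — rather
than two $x$-parameterized phase integrals — handles non-monotone segments
and post-recovery ringing ($x < 0$) without re-sorting; on loops whose
phases are each monotone in $x$ the two formulations agree to floating-point
precision, which the suite verifies over 1000 random loops.

**Slopes.** The 10%-of-MAD point is located on the loading phase only, at
the first crossing, with linear interpolation to exactly $0.1\,\mathrm{MAD}$
(neither an occurrence rule nor an interpolation rule is forced by the
definitions, so the most deterministic choice is used). Window membership
for `S_low`/`S_high` uses closed intervals in $x$ and a fit needs at least
3 samples; ties at the maximum displacement break to the earliest sample.
A loading span shorter than the 120 µm window raises a classed error rather
than silently fitting a truncated window, and `compute_all_metrics()`
converts such errors into NA fields with the reason recorded in `flags`.

**Units.** Displacement is carried in micrometers (the natural scale of the
segmentation) and converted to meters inside every energy and slope
computation, so HA is reported in joules and slopes in N/m. For a 120.8 mN
pulse deforming the apex by ~1 mm, loop energies are of order
$10^{-5}$–$10^{-4}$ J.

## The synthetic-data generator

`generate_force_pulse()` renders the stimulus. The default is a
raised-cosine of 32 ms total duration sampled at 50 kHz (1600 samples — the
record geometry of the instrument) peaking at 120.8 mN, the calibrated peak
force corresponding to an 18.18 kPa peak sensor readout. The true pulse
shape of a commercial tonometer is not published; a raised cosine is
smooth, zero-ended and has a closed-form integral, which makes it a good
test vector, but it is a stand-in, not a claim about any device. A
`gamma` shape is available for asymmetry studies, and a `delay` parameter
(4 ms in the cohort designs) inserts the quiet pre-stimulus interval that
defines the displacement baseline window.

`render_mscan()` draws each A-scan as two Gaussian bands of width
`band_sigma` (default 16 µm, an effective axial point-spread) over a low
background: the anterior at `anterior_depth + x(t)` and the posterior one
optical thickness below. Optical thickness is physical CCT times the
corneal group index (1.376), and shrinks linearly with $x(t)/\max x$ to
`compression_fraction` (default 3%) at peak deformation — a slight, fully
recovering compression of the tissue at maximum deformation. Speckle is
modeled as unit-mean multiplicative noise with standard deviation
`speckle_contrast` (a shifted exponential: 1 recovers fully developed
speckle, 0.5 is the default test condition), plus additive Gaussian
background noise. Every generator is a pure function of its spec and seed.

Default phantom values are chosen for an ex vivo porcine eye under this
stimulus: resting CCT 950 µm, $k$ mapped affinely from IOP as
$k = 100 + 3\,\mathrm{IOP}$ N/m (giving MAD from roughly 1.05 mm at
5 mm Hg down to 0.59 mm at 35 mm Hg — the magnitude and direction seen in
porcine inflation data), damping 0.10–0.18 N·s/m across the cross-linking
(CXL) stages so dissipation rises as the tissue state changes, and
per-stage resting CCT of 900/770/576 µm so the full CXL progression thins
the cornea by 36%, the scale reported for dextran-based riboflavin
protocols. A per-eye log-normal stiffness factor (5% CV, constant across
conditions) makes cohorts realistic while keeping paired designs paired.

**What the phantom does not emulate.** The Kelvin–Voigt element is linear:
it cannot produce the J-shaped loading curve, the inflation-cycle memory
(ascending/descending asymmetry), or any nonlinear stiffening of real
tissue. That is intentional — trend tests use the phantom precisely
because its ground truth is analytic, and the memoryless design doubles as
a null model: the experiment pipeline verifies that ascending and
descending metric curves *coincide* on the phantom, so any separation seen
in real data is attributable to tissue, not to the pipeline. J-shape
properties (`S_high > S_low`) are tested on constructed bilinear and
exponential loading curves instead. Passing the synthetic suite therefore
demonstrates the correctness of the numerics and the segmentation under
speckle, not biological fidelity.

## Segmentation choices

Per column, the anterior surface is the first peak from the top exceeding
the column background (median) by `min_prominence` (default 0.25) of the
column's dynamic range — a relative criterion, so segmentation is invariant
to global intensity rescaling. The posterior is the next peak at least
`min_separation_um` (default 300 µm) deeper. Peaks are refined to subpixel
by a 3-point parabolic fit after boxcar smoothing (`smooth_px` = 5), and
surface traces are median-filtered over `median_width` = 9 columns.
Columns with no detection are flagged invalid and kept as NA in the
`surface_pair` (auditable QC); they are linearly interpolated only in the
derived displacement trace, with per-sample flags. More than 20% invalid
columns is treated as a failed segmentation. With the default parameters
the round trip render → segment → displacement recovers the input trace
with RMSE below 2 µm at speckle contrast 0.5 and 8 µm/px pitch.

CCT is reported as *physical* thickness: the optical posterior–anterior
separation divided by the group index, which is stored in the output so
optical values remain recoverable. `cct_aft` is averaged over the trailing
run of samples with $|x| < 5\%$ of MAD — a recovery criterion chosen to be
robust and testable rather than imposed by any definition.

## Statistics and experiment designs

`run_inflation_experiment()` executes the cyclic IOP design (ascending
5→35 mm Hg then descending, 5 mm Hg steps, top level not repeated) through
the full simulate → render → segment → calibrate → metrics chain, and
reports per-level means ± SD plus the Pearson correlation of each metric
with IOP. `run_cxl_experiment()` runs the three-stage CXL design (EPI_OFF,
RS, RS_UV at 15 and 25 mm Hg), adds the CCT-corrected MAD
(`mad_over_cct = MAD / cct_bef`), and compares consecutive stages with the
pooled two-sample t test at $\alpha = 0.05$. The unpaired form is used for
stage comparisons — matching the stated analysis — even though the design
is paired; eye identity is preserved in the long results table so a paired
re-analysis is a one-liner for the user. Both t test and Pearson R are
thin validated wrappers over the standard library routines.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script use: 1600-sample pulses
at 50 kHz; 1000 random loops for the area-oracle property; 50 speckled
phantoms (1600 × 448 px at 8 µm/px) for segmentation recovery; inflation
cohorts of 2 eyes × 13 conditions and CXL cohorts of 2 eyes × 6 conditions
rendered noiselessly for trend checks. These sizes give stable statistics
while keeping a full run in the tens of seconds; all are spec fields, so
larger studies only change a number. Every random quantity flows from an
explicit seed, and identical spec + seed reproduce byte-identical result
CSVs.

## Known limitations

* Only the apex column is modeled; full-field deformation, air-jet fluid
  dynamics and whole-globe retraction are out of scope.
* The force calibration is affine; the fit $R^2$ is reported so a
  nonlinear sensor would be visible, but no nonlinear model is provided.
* A fixed latency between the pressure-sensor and OCT streams would bias
  HA; the pipeline assumes a shared trigger and provides no latency
  estimator.
* Real-tissue descriptor values (from porcine or human eyes) cannot be
  reproduced by the linear phantom and are not targets of the test suite.

```{r example, eval = FALSE}
# one synthetic stimulation, end to end
f  <- generate_force_pulse(pulse_spec(delay = 0.004))
ph <- phantom_spec(kv = kv_params(k = 150, c = 0.12), seed = 1)
x  <- simulate_eye_response(f, ph)
m  <- render_mscan(x, ph)
s  <- segment_surfaces(m)
xd <- displacement_from_surfaces(s, m, baseline_window = 1:190)
compute_all_metrics(xd, f, cct_at_instants(s, xd))
```
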