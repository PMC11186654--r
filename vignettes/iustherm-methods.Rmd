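---
title: "Acoustic-biothermal modeling of catheter-based interstitial ultrasound ablation"
author: "iustherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic-biothermal modeling of catheter-based interstitial ultrasound ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iustherm)
```

## The problem

Catheter-based interstitial ultrasound (CBUS) applicators are linear
arrays of 1-4 tubular piezoelectric transducers (10 mm long, 1.5 mm OD,
6.5-9 MHz) inside a water-cooled 2.4 mm OD implant catheter.  Driven at
surface intensities of roughly 8-20 W/cm², they coagulate a volume of
tissue around the catheter within minutes; sectored transducers (90° or
180° active azimuth) steer the energy away from structures that must be
spared (urethra, rectum, neurovascular bundles), which makes the
technology attractive for focal ablation of prostate cancer.  Planning
such a treatment requires predicting, for a given implant geometry and
drive schedule, the three-dimensional temperature history and the
resulting thermal-damage volume.

`iustherm` implements the full forward chain: acoustic power deposition
of sectored tubular arrays, an explicit finite-difference time-domain
(FDTD) solution of the Pennes bioheat equation with convective cooling
boundaries and thermal-dose-dependent perfusion shutdown, CEM43 dose
accumulation, ablation-zone metrology, temperature-feedback control, and
the surrounding planning workflows (parameter-sweep lookup tables, NRRD
dose-cloud export, scene configs, synthetic anatomy, STL voxelization).

## Acoustic model

Each tubular element radiates a cylindrically spreading, exponentially
attenuated intensity field

$$I(r) = I_0 \frac{r_0}{r}\, e^{-2\alpha f (r - r_0)},$$

where $r$ is the perpendicular distance from the applicator axis, $r_0$
= 0.75 mm the transducer surface radius, $\alpha$ (Np/m/MHz) the
acoustic attenuation of the local tissue and $f$ the drive frequency in
MHz.  Attenuation is taken equal to absorption (all attenuated energy is
deposited locally), and the volumetric heat source is $Q = 2\alpha f I$.
Contributions of all elements and applicators superpose.

Three geometric choices close the model:

* **Axial collimation.** Each element radiates only within its own
  axial span (sharp cut at the element ends).  This is the standard
  tubular-source approximation for these devices and is what limits the
  lesion length to roughly the active array length; without it a single
  element would heat an infinite cylinder.
* **Sharp sector edges.** Sectored elements apply $I_0$ uniformly over
  the active azimuth and nothing outside it, with no angular
  apodization; the boundary half-angle is included.
* **Local attenuation only.** Each voxel uses its own $\alpha$ both in
  the exponent and in the absorption factor; the ray path through mixed
  tissue is not traced.  The scenes the model targets are close to
  homogeneous, so the committed error is small compared to the
  uncertainty in $\alpha$ itself.

Voxels within the catheter outer radius (1.2 mm) are non-tissue: they
receive no deposition and are frozen out of the thermal update.  The
catheter track is modeled as passing through the whole domain along the
applicator line.

## Thermal model

Tissue temperature follows the Pennes bioheat transfer equation

$$\rho_t C_t \frac{\partial T}{\partial t} =
  k\nabla^2 T - \omega_b C_b (T - T_b) + Q,$$

with $T_b$ = 37 °C, $C_b$ = 3720 J/kg/°C, discretized with a 7-point
Laplacian and forward-Euler time stepping on a uniform grid (default
$\Delta x$ = 0.5 mm, $\Delta t$ = 0.1 s).  `stabilityCheck()` enforces
$\Delta t \le \rho c / (6k/\Delta x^2 + \omega_b C_b + h_v)$, the
conduction bound adjusted for the perfusion sink and the linearized
convective cooling term; the default configuration sits at about a third
of the bound.

**Cooling boundaries.** The circulating water in the catheter (and
optionally an irrigated urethral catheter) is modeled by a convective
condition $k\,\partial T/\partial n = h(T_w - T)$ with $T_w$ = 25 °C and
$h$ = 500 W/m²/°C, applied across every voxel face that separates tissue
from a cooled region; a tissue voxel with $n$ cooled faces receives the
volumetric term $n\,h/\Delta x\,(T_w - T)$.  The catheter wall
(< 0.5 mm) is below grid resolution and is treated as thermally thin.

**Domain edges** are zero-flux (adiabatic).  The heated zone is small
compared to the 6 cm domain, and the suite verifies that enlarging the
domain to 8 cm changes the temperature at 2 cm radius by well under
0.1 °C, so the choice of edge condition is immaterial for the scales
simulated.

**Properties** are constant with temperature; only blood perfusion
changes dynamically: once the local thermal dose reaches 300 CEM43
minutes, perfusion at that voxel is set to zero permanently (vascular
shutdown).  Discrete vessels are not modeled.

## Thermal dose and metrics

Thermal dose is accumulated every solver step as cumulative equivalent
minutes at 43 °C,

$$TD(t) = \int_0^t R^{\,43 - T(t')} \mathrm{d}t', \qquad
R = \begin{cases}0.25 & T < 43\,°C\\ 0.5 & T \ge 43\,°C,\end{cases}$$

with the boundary value 43 °C on the $R = 0.5$ branch.  $TD \ge 240$ min
delineates complete necrosis; 600 min is carried as a conservative core
contour.  The ablation zone is measured in the applicator frame the way
sectioned lesions are measured: `d1` the maximum perpendicular reach
from the axis (along the sector bisector for directional devices), `d2`
the width perpendicular to the bisector in the central transverse plane
of the array, `d3` the axial extent, plus the voxel-counted volume.
Extents use voxel centers without sub-voxel interpolation, so each value
carries about one voxel (0.5 mm) of measurement precision; the 600 min
zone is nested inside the 240 min zone by construction.

## Feedback control

Two controller types emulate invasive temperature sensing at monitoring
points (TMPs, sampled by trilinear interpolation every 1 s; between
updates the last decision holds):

* **Binary** (bang-bang): power fully on while $T \le T_{reg}$
  (boundary included), off otherwise; mimics an ideally tuned PID.
* **Pilot point**: power on while $T < T_{thres}$; the first sample at
  or above the threshold switches power off and latches permanently
  (treatment ended), while dose continues to accrue through cooldown.

Controllers gate whole applicators by default; multiple controllers
compose by taking the product of their decisions, and any pilot
termination wins.  The per-update decisions, TMP temperatures and power
scales are logged.

## Numerical implementation

The time loop is compiled (C++ via Rcpp).  Per step it performs the
stencil update, accumulates dose, applies perfusion shutdown and — on
1 s boundaries — evaluates controllers.  Two implementation details
matter for exactness guarantees:

* The hot loop folds the perfusion sink and cooling into per-voxel
  linear coefficients ($c_0 - c_1 T$), algebraically identical to the
  reference update but differing in floating-point grouping.  The
  exported single step `bhteStep()` uses the reference arithmetic and is
  what the test suite matches bit-for-bit against a plain per-voxel R
  loop.
* In-loop dose accrual below 38 °C is truncated (rate $< 2\times10^{-4}$
  CEM-min per minute; at most ~0.01 min over a 12-minute run, i.e.
  0.005 % of the necrosis threshold), and the in-loop exponential is
  evaluated in single precision (relative error ~1e-7).  The R-level
  `accumulateDose()` is exact double precision; the dose identities of
  the test suite run through it.

## Tissue properties

`defaultTissueTable()` carries the acoustic and thermal constants used
for all default scenes, transcribed from the standard values of the
interstitial-ultrasound modeling literature: prostate/soft tissue
$\alpha$ = 5.75 Np/m/MHz (0.5 dB/cm/MHz), $k$ = 0.51 W/m/°C, $\rho$ =
1045 kg/m³, $c$ = 3760 J/kg/°C, nominal perfusion 2.5 kg/m³/s (planning
sweeps bracket 0-5); muscle and liver entries (used by the ex-vivo
benchmarks at zero perfusion) differ mainly in attenuation (6.6 and
5.2 Np/m/MHz).  Reported attenuation for these tissues spans roughly
0.4-0.7 dB/cm/MHz across the literature, and the predicted lethal-zone
extents are sensitive to the choice at the ±10-20 % level — larger
$\alpha$ concentrates deposition near the catheter (shorter, squatter
zones and more heat lost to the cooled wall), smaller $\alpha$ spreads
it radially.  This is the dominant systematic uncertainty of the
package's absolute predictions and the reason benchmark comparisons are
quoted with explicit margins.

## Synthetic anatomy

`makeSyntheticAnatomy()` builds the patient-like scene used to exercise
multi-structure workflows: an ellipsoidal gland (default semi-axes
20 × 17.5 × 15 mm, a typical 40 × 35 × 30 mm prostate) centered in the
6 cm domain, a 2.5 mm radius urethra along the gland axis, a rectum-wall
shell posterior to the gland, and seeded ellipsoidal target lesions
(0.1-12 cm³, the clinically reported range) placed by rejection sampling
fully inside the gland and clear of the urethra.  The generator is
bit-reproducible for a fixed seed.  It emulates the geometry and
topology of segmented anatomy — not its shape irregularity, tissue
heterogeneity or true organ contours — so passing tests on synthetic
scenes demonstrate the mechanics of multi-structure planning (masks,
cooling surfaces, TMP placement), not patient-level accuracy.

## Planning workflows

`runSweep()` enumerates the Cartesian product of sector × element count
× intensity × heating time × perfusion on the generic model and tabulates
`d1/d2/d3/volume` at both dose contours — the lookup-table ("a priori")
planning library.  Intensity levels are supplied explicitly by the
caller (the published 360-case library does not factor uniquely into
the listed level counts); the default frequency is 7.5 MHz, the value
quoted with the published two-element lookup excerpt.  Dose and
end-of-sonication temperature clouds export as gzip-encoded NRRD volumes
(spacing recorded in mm) for overlay in external viewers, and
`formatLookupTable()` reproduces the nominal (low-high) perfusion
presentation.  `loadScene()` reads a YAML scene config with the solver
defaults applied and the stability bound checked before any run;
`exec/iustherm` exposes `simulate`, `sweep`, `synth` and `validate`
subcommands.

## Benchmarks and problem sizes

The acceptance runs reproduce the generic-model extrema at the study
conditions (6 cm cube, 0.5 mm, 0.1 s, 7.5 MHz): the maximal
configuration (360°, 4 elements, 20 W/cm², 10 min + 2 min cooldown, zero
perfusion) and the minimal one (1 element, 8 W/cm², 5 min, 5 kg/m³/s,
each sector type).  The ex-vivo benchmark suite (`validationCases()`)
reconstructs previously reported coagulation experiments — single 360°
and 180° applicators (9 MHz, 2 elements) in muscle and two/three
clustered 360° applicators (7 MHz, 2 cm spacing) in liver, zero
perfusion — with case intensities and times chosen once within the
documented protocol ranges (7.1-13.5 W/cm², 3-10 min) and reference
extents taken from the reported measurement summaries.  The automated
test suite runs these benchmarks at 1 mm resolution to keep its runtime
moderate; the grid-convergence test bounds the 1.0 → 0.5 mm change of
`d1` below 5 %.

Known limitations: no temperature dependence of acoustic or thermal
properties (attenuation rises during coagulation, which published
sensitivity studies find would raise peak temperatures and slightly
shrink volumes); no discrete vasculature; sharp sector edges ignore
diffraction; no tissue water vaporization above ~100 °C, so peak
temperatures at extreme drive levels are nominal; and absolute zone
sizes inherit the tissue-property uncertainty discussed above.
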