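---
title: "Methods: field modelling of pulsed-field ablation lesion depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field modelling of pulsed-field ablation lesion depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific background

Pulsed-field ablation (PFA) kills myocardium non-thermally: trains of
microsecond high-voltage pulses permeabilize cell membranes, and cells
exposed to a field magnitude at or above the irreversible-electroporation
(IRE) threshold die. Because the pulses are short, heating is negligible and
the lesion boundary is, to a good approximation, an *iso-field surface*.
Predicting a PFA lesion therefore reduces to an electrostatics problem:
compute the electric field around the catheter, threshold it, and measure
how deep the supra-threshold region extends into the tissue.

`pfasim` models a two-electrode (bipolar) catheter lying horizontally in a
blood pool above a flat myocardial slab:

* Two cylindrical electrodes (default 2 mm long, 2.3 mm diameter) separated
  by a 4 mm insulated gap on a common shaft, driven at +V/2 and -V/2.
* The catheter axis is parallel to the endocardial surface at a controlled
  elevation (0 mm = full contact, up to 5 mm).
* Blood above the surface, homogeneous myocardium below it (default slab
  thickness 15 mm), in a 40 x 40 x 35 mm box.

## Governing equation and discretization

On pulse time-scales the quasi-static approximation holds, and because
tissue and blood are conductive the governing equation is the steady-current
(volume-conductor) equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with the field magnitude $E = |\nabla \varphi|$. Absolute conductivities
only set the total current; the *field pattern* depends on the
blood:myocardium conductivity ratio, which is the model's single calibrated
parameter (see below). An `electrostatic` mode (permittivities instead of
conductivities) is provided for comparison; at equal coefficient ratios the
two modes produce the same potential.

The equation is discretized with a cell-centred finite-volume scheme on a
uniform voxel grid: a 7-point stencil whose face coefficients are the
harmonic means of the two adjacent voxel conductivities. Harmonic averaging
reproduces the exact one-dimensional series-resistance behaviour across the
blood/tissue interface. Electrode voxels are Dirichlet nodes (the metal is a
perfect conductor, so each electrode fills its voxels at a fixed potential);
the insulated shaft is zero-conductivity (zero-flux); the outer boundary is
insulated by default, with a grounded option. The symmetric positive-definite
system is solved matrix-free with Jacobi-preconditioned conjugate gradients
in C++ (via Rcpp); a relative-residual tolerance of `1e-8` is the default.
Re-solves after small conductivity changes warm-start from the previous
potential, which makes calibration cheap.

Because the equation is linear in the applied voltage, one *normalized*
solve at 1 V gives every voltage for free: the depth at voltage $V$ is the
crossing of the normalized field with threshold $E_{IRE}/V$. Voltage sweeps
and minimum-voltage searches therefore cost a single solve per geometry.

## Lesion-depth definition

The IRE threshold defaults to 268 V/cm (measured for healthy myocardium; it
is a first-class parameter because waveform changes shift it). The reported
lesion depth (`depth_mm`) is the **centerline depth**: the field is sampled
down the vertical line through the midpoint between the electrodes, and the
deepest threshold crossing is located with sub-voxel linear interpolation.
The deepest supra-threshold tissue voxel anywhere (`depth_max_mm`) is also
returned; near contact it is slightly larger because the field bulges under
each electrode rather than under the gap. The centerline definition is the
one that reproduces the in-vivo anchor depths and is the package default;
both numbers are always available.

## Calibration and validation

Published tissue properties vary widely (blood roughly 0.7 S/m, myocardium
0.05-0.5 S/m depending on source and frequency), so the model is anchored
once: `calibrate_conductivity_ratio()` tunes the blood:myocardium ratio in
[1, 10] (holding myocardium at 0.20 S/m) until a 500 V contact delivery
produces a 2.28 mm lesion. The search is a clamped secant iteration on the
monotone depth-vs-ratio response, warm-starting each solve; it typically
converges in 4-6 solves. Empirically the depth *increases* with the ratio:
a more conductive blood pool concentrates the potential drop, and hence the
field, in the resistive tissue layer beneath the catheter.

All other outputs are predictions, not fits: the 2200 V depth, the
2500 V depth, the dose-response table, the contact sweeps, and the
minimum-voltage searches all come from the calibrated model without further
adjustment. `validate_against_invivo()` compares predictions with the
published porcine depths (2.25 ± 0.85 mm at 500 V, n = 6; 6.5 ± 1.7 mm at
2200 V, n = 4) and their Student-t 95% confidence intervals, which
`confidence_interval()` reproduces from the printed mean/SD/n.

## Verification

Two closed-form oracles check the solver end-to-end:

* **Parallel plates.** A homogeneous block whose first and last z-layers are
  electrodes: the discrete solution is an exact linear ramp with
  $|E| = V/g$, where the gap $g$ is the distance between the electrode
  *inner faces* (the conductor fills its cell, so $g = (n-2)h$).
* **Two point charges.** Single-voxel electrodes at $\pm a$ in a homogeneous
  medium: along the perpendicular bisector the analytic field is
  $E(y) = 2kqa/(a^2+y^2)^{3/2}$. The numerical profile matches the analytic
  shape to within 5% for $y \in [a, 5a]$ (the charge is fitted at $y = a$,
  so the comparison tests the profile shape, not an absolute scale).

Property tests additionally enforce the discrete maximum principle,
potential antisymmetry/field symmetry across the device's mirror planes,
electrode current balance, linearity (sweep-by-scaling vs. re-solve), and
the scaling identity depth(V, thr) = depth(cV, c·thr).

## Numerical parameters and problem sizes

* **Production spacing 0.25 mm** (full 40 x 40 x 35 mm domain, about 3.6 M
  voxels): used by `default_config()` and the headline-number script; a
  cold solve takes a few minutes on one CPU.
* **0.4 mm** is used by the package's acceptance tests (same full domain,
  under a minute per solve) — the anchor depth is still reachable there.
* **0.5 mm on reduced extents** is used by the fast unit/property tests.

Grid-convergence behaviour: the electrode cylinder (2.3 mm diameter) is
stair-stepped, so the scheme converges at roughly first order in the voxel
pitch near the device, and centerline quantities change by several percent
between 0.5 mm and 0.25 mm; refinement beyond 0.25 mm changes depths by
considerably less. The threshold-crossing interpolation also interacts with
voxel alignment, producing small non-monotonic wiggles in depth vs. spacing.

## Limitations

* The outer-boundary condition matters at the percent level: switching the
  default insulated box to a grounded one moves the mid-depth centerline
  field by about 3% at the default extents. Larger boxes reduce this.
* Elevated-catheter predictions are less accurate than contact ones: with
  the one-point contact calibration the model tends to over-predict depth at
  2 mm elevation (the minimum voltage for a 3 mm lesion comes out several
  hundred volts below the reported in-vivo-matched value). A contact-quality
  dependent threshold or a non-flat tissue surface would be needed to close
  that gap.
* Single homogeneous tissue layer; no trabeculation, fibrosis, or thermal
  effects (`temperature_update()` exposes a linear conductivity-temperature
  law for sensitivity studies but no heat equation is solved).
* The IRE threshold is treated as a sharp deterministic iso-surface; real
  electroporation has pulse-number and waveform dependence.

## Worked example

```{r, eval = FALSE}
library(pfasim)

# calibrate once (production grid; takes a few minutes)
cal <- calibrate_conductivity_ratio()
cal$ratio

# dose-response at contact from the calibrated normalized solve
sweep <- run_voltage_sweep(catheter_spec(), fm_norm = cal$field)
sweep

# minimum voltage for a 3 mm lesion at contact
min_voltage_for_depth(3, fm_norm = cal$field)

# compare with the published in-vivo depths
md <- data.frame(voltage_V = c(500, 2200),
                 depth_mm = sapply(c(500, 2200), function(v)
                   lesion_depth_at(cal$field, v)$depth_mm))
validate_against_invivo(md)
```

A faster, coarse-grid version of the same pipeline (suitable for trying the
package out) replaces the calibration call with

```{r, eval = FALSE}
cal <- calibrate_conductivity_ratio(spacing = 0.5,
                                    extents = c(24, 24, 16),
                                    tissue_depth = 8)
```
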