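---
title: "Models and methods behind mrlqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrlqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlqa)
```

mrlqa implements the image-quality assurance chain of a 1.5 T MR-linac:
daily image-quality metrics, 3D geometric distortion, gantry-resolved
B0/B1 field mapping, quantitative T1/T2/ADC estimation, and longitudinal
tolerance and trend bookkeeping. This vignette records the models, the
assumptions of the synthetic phantom generator, and the numerical and
design choices, in the order a physicist meets them.

## Coordinate and noise conventions

All geometry lives in machine coordinates: millimetres, origin at
isocenter. A voxel with 1-based array index $(i,j,k)$ has its *center*
at `originMm + (index − 1) · spacingMm`; generators place volumes so the
grid center coincides with isocenter. This convention is stated once
here and used everywhere.

Magnitude noise is simulated by adding independent Gaussian noise of SD
$\sigma$ to the real and imaginary channel of the noiseless signal and
taking the magnitude. Vial and phantom interiors therefore carry Rician
noise and signal-free background is Rayleigh, with background
mean/SD $= \sqrt{\pi/2}/\sqrt{2-\pi/2} \approx 1.913$ — a property the
test suite checks, and the reason the SNR metric divides the background
SD by $0.655 = \sqrt{2-\pi/2}$ by default (raw-SD behaviour is a flag,
and the choice is recorded in the result's attributes). No scanner
noise model beyond this is attempted: no coil-array covariance,
eddy currents, susceptibility warps or chemical shift, so passing tests
demonstrate correctness of the estimators, not robustness to artifacts
the generator never produces.

## Synthetic phantoms

*Image-quality sections.* The linearity section is a 7×7 lattice of
5 mm holes at 25 mm spacing with the four corners absent (45 holes,
spanning 150 mm — the only layout consistent with the phantom's printed
hole count, spacing and section size). The slice-profile section is an
opposing wedge pair with slope 0.2 (through-plane mm per in-plane mm),
so a 5 mm slab projects to a 25 mm plateau; rectangular profiles are
rendered with an edge ramp two in-plane samples wide, which puts the
half-maximum crossing between two samples of the same linear segment and
makes the interpolated FWHM exact. The resolution section is a uniform
block whose edges snap to voxel boundaries by default: the discrete
line-spread function of a box-sampled edge otherwise oscillates between
one and two samples depending on the sub-voxel edge phase, which is a
property of sampling, not of the scanner.

*Fiducial phantom.* Seven plates 55 mm apart carry markers on a 25 mm
half-offset square lattice cut at radius 235 mm — exactly 276 markers
per plate, 1932 in total, with the central plate at isocenter. Markers
are rendered as Gaussian blobs (σ = marker diameter/4) evaluated over a
±4σ support: a sampled Gaussian's intensity centroid equals its center
to within an exponentially small aliasing term, so ground-truth marker
positions are recoverable to well under 0.01 voxel and recovery tests
measure the *analysis*, not rendering quantization. Fields whose
displacement exceeds half the marker spacing are refused at generation
time, mirroring the pairing radius of the detector.

*Field cylinder.* A 40 cm uniform disk. The default ground truth uses a
linear static B0 profile plus a gantry-dependent linear perturbation
$w(\theta) = (1-\cos\theta)/2$ peaking at gantry 180°, calibrated so the
raw in-plane range over the 35 cm analysis circle at 180° is 3.05 ppm
with the gantry-induced part (18 Hz peak-to-peak) an order of magnitude
smaller; B1 defaults to a smooth profile with mean absolute deviation
1.2 % from nominal. These defaults reproduce the regime a well-shimmed
1.5 T MR-linac operates in; they are configuration, not measurement.

*Vial arrays.* The relaxometry layout places 14 vials on a 60 mm ring;
the diffusion layout one center vial plus two rings of six (radii 30
and 65 mm), each ring spanning the full value range. Nominal values of
the physical phantoms are user-supplied configuration; the shipped
defaults are synthetic stand-ins (T1 log-spaced 500–2000 ms with
T2 = T1/5; ADC 0.4–1.1 × 10⁻³ mm²/s with 1.1 × 10⁻³ at the center) and
are labelled as such.

*Determinism.* Every generator seeds R's RNG from `GroundTruth@seed`;
identical seeds give bit-identical volumes.

## Image-quality metrics

Uniformity is $(\max-\min)/(\max+\min)\times 100\,\%$ over the ROI after
an optional in-plane Gaussian low-pass (default FWHM of one voxel, so a
single noise voxel cannot own both extrema; `smoothingMm = 0` disables
it). Linearity detects hole centroids (Otsu threshold, 8-connected
components, intensity-weighted centroids over a padded bounding box —
padding removes the threshold-truncation bias that would otherwise
quantize sub-voxel positions), pairs them to the machined lattice after
a translation estimate, and measures center-node→outermost-node
distances along the eight compass rays; the odd 7×7 grid guarantees a
center node, so each direction is a true radius. Slice-profile FWHM
uses linear interpolation between the bracketing samples at half
maximum — no spline fitting, keeping the estimator deterministic — and
the integral is the equivalent width, $\sum p / \max p \times$ sample
spacing, which equals the FWHM exactly for a rectangular profile.
Pixel size is reported as the FWHM of the line-spread function obtained
by discrete differentiation of the edge-spread function; the vendor's
internal convention is undocumented, so this choice is fixed, recorded
in the output attributes, and the published tolerances are applied to
this quantity.

## Distortion analysis

Detection thresholds the volume (Otsu on a 256-bin histogram), labels
3D connected components on the 6-neighbour voxel graph, and computes
intensity-weighted centroids over each component's padded bounding box
after subtracting the box's median (zero for noiseless volumes, the
Rayleigh background level otherwise — the subtraction keeps the
background mean from pulling centroids toward the box center while
leaving the blob symmetric about its true position). Setup error is
removed by default with a rigid (translation + rotation, Kabsch)
least-squares alignment of detections onto the machined grid before
vectors are computed — the vendor tool's behaviour here is unknown, so
the flag `align = FALSE` exposes the other convention; the test suite
exercises both branches. Pairing accepts the nearest expected marker
within half the minimum grid spacing; beyond that a marker is *missing*
rather than grossly distorted — a silently wrong pairing is worse than
a reported dropout. Distortion magnitude is the Euclidean norm of the
3-vector (tolerances are scalar), and the per-DSV maximum is taken over
markers whose *known* position lies inside the isocenter-centered
sphere, which makes the maximum provably non-decreasing in DSV.

## Field maps

B0 comes from the dual-echo phase difference
$f = \mathrm{wrap}(\varphi_2-\varphi_1)/(2\pi\,\Delta TE)$, unambiguous
within $\pm 1/(2\Delta TE)$ (±333 Hz at ΔTE = 1.5 ms). No unwrapping is
applied by default — QA fields sit far inside the range — but a wrap
flag propagates from the generator or is raised when reconstructed
values reach the range boundary. The ppm channel divides by
$f_0 = \gamma B_0$ = 63.866 MHz.

The dual-TR B1 reconstruction inverts
$\alpha = \arccos\!\big((rn-1)/(n-r)\big)$, $r = S(TR_2)/S(TR_1)$,
$n = TR_2/TR_1$ — the long-T1 (actual-flip-angle) approximation of the
two-TR spoiled steady state. No reconstruction equation is published
for the scanner's maps, so the simulator uses the exact forward
counterpart of this inversion,
$S_1 \propto \sin\alpha\,(n+\cos\alpha)$,
$S_2 \propto \sin\alpha\,(1+n\cos\alpha)$, making the round trip the
identity (verified to < 0.01° for α between 10° and 85°); the long-T1
assumption is the documented caveat when applying the inversion to data
from short-T1 phantoms. Ratios outside the model domain $(1/n, 1)$ are
masked and counted, never clamped.

Gantry sweeps subtract the voxelwise mean map across angles from each
B0 map to isolate rotation-induced changes and report the peak-to-peak
(literal 0th/100th percentile range by default; 1st/99th available for
robustness) per angle both raw and mean-subtracted — the published
worst-case figure keeps the static contribution, so both are always
reported. The analysis region is a 35 cm circle eroded by one voxel to
avoid rim partial-volume effects. B1 sweeps report the per-angle mean
absolute deviation from 100 % and its across-angle mean ± SD. The
displacement bound ΔB₀/G_read converts a field offset into millimetres
of readout shift: 3 ppm at 1.5 T under 15 mT/m is 0.30 mm.

## Quantitative MRI

T1 uses the variable-flip-angle linearization
$S/\sin\alpha = E_1\,S/\tan\alpha + S_0(1-E_1)$ solved per voxel by
*unweighted* ordinary least squares — the estimator as practised, kept
deliberately, with $T1 = -TR/\ln m$ valid only for slope $m \in (0,1)$.
Masked voxels (invalid slope, non-positive signal, $R^2$ below 0.95 for
fits with more than two points, or a signal that does not vary with flip
angle and therefore carries no $E_1$ information) are NA, never zero.
T2 and ADC are log-linear least squares on TE and b; the dummy echo
(annotated by the generator, one echo spacing before the train, 5 %
below the mono-exponential curve to emulate the stimulated-echo
elevation every later echo shares) is discarded by default, and fitting
*with* it demonstrably overestimates T2 — the direction the discard rule
exists to prevent.

The flip-angle optimizer brackets the two roots of
$S(\alpha) = f\,S(\alpha_E)$ on either side of the Ernst angle
$\alpha_E = \arccos e^{-TR/T1}$ with `uniroot` at tolerance 1e-12 and is
cross-checked against a 0.01° grid search in the tests. The fractional
criterion defaults to $f = 0.71$ and the T1 range is reduced to its
midpoint by default (1500 ms for the 1000–2000 ms design range, which
yields the {4°, 22°} pair); averaging the per-bound angle pairs is the
configurable alternative.

Bias is $(\text{measured}-\text{nominal})/\text{nominal}\times100\,\%$
of the across-session mean of ROI means (1 cm circular ROIs on the vial
centers); COV is the SD of session means over their mean. The SD uses
the population (n) denominator by default — the convention under which
three session means {100, 101, 99} give the reference value 0.816 % —
with the sample (n−1) variant behind `sampleSd = TRUE`. A single
session yields COV = NA, never 0. Spearman dependence tests use average
ranks and an exhaustive-permutation two-sided p-value for n ≤ 8
(feasible and exact at these vial counts), the large-sample
t-approximation above that.

For the stochastic validation the noise level is set by image SNR:
`qmriNoiseSd()` divides the mean noiseless vial signal across the series
by the target SNR. Referencing $\sigma$ to the equilibrium $S_0$
instead would leave spoiled gradient-echo images at an effective SNR
near 6 (the spoiled signal at TR = 20 ms is ~6 % of $S_0$), a regime no
clinical protocol operates in. The test suite runs 50 sessions at image
SNR 100 on the 14-vial relaxometry and 13-vial diffusion layouts (ADC
analyzed in the inner ring, as on the physical phantom) and checks that
median bias and COV stay inside the published reproducibility envelopes;
problem sizes (160² single-slice sessions, 50 realizations) were chosen
as the smallest at which the envelope check is meaningfully powered.

## QA records and trends

Tolerance strings follow the printed operator exactly: `"> 59"` and
`"< 47"` are strict, `">="`/`"<="` and closed intervals include their
boundaries; the boundary semantics are fixed by convention since
published tables never test them. Trends are OLS of value on date
(ISO-8601 only), annualized by ×365.25, optionally normalized to the
fitted baseline so drift reads in percent per year. Change-point
flagging is a two-sided CUSUM (slack 0.5σ, threshold 4σ of the
first-30-session baseline), purely a monitoring aid patterned on how a
gradual SNR decay is caught in practice; it is not a published
algorithm. Reports serialize with fixed key order and full-precision
numbers, so identical inputs give byte-identical JSON.

## Known limitations

The generator's idealizations bound what the tests can claim: no
k-space simulation, no EPI distortion or eddy currents, no coil
sensitivity profiles, no B1-corrected VFA, no multi-compartment T2 or
IVIM diffusion. The dual-TR inversion assumes long T1. The discrete
line-spread-function pixel size depends on edge/voxel phase, handled
here by boundary snapping. Tolerance tables ship as editable JSON
(`inst/extdata/tolerances.json`) and vial nominals are always
user-supplied — the shipped values are synthetic stand-ins, not
metrology.
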