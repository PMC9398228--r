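# mrlqa

Quality-assurance analysis for the MRI side of a 1.5 T MR-linac
(an MRI scanner integrated with a linear accelerator for
MRI-guided radiotherapy), built for medical physicists who need the full
QA chain — image-quality metrics, geometric distortion, field
homogeneity, quantitative biomarkers and longitudinal bookkeeping — as
reproducible, scriptable R code rather than vendor black boxes. Every
analysis stage is exercised against a synthetic phantom generator with
known ground truth, so the whole pipeline is testable without scanner
time.

## What it computes

**Daily image quality** (from the periodic image-quality phantom):

- SNR = mean(signal ROI) / noise, with the background noise estimated
  from the magnitude background SD divided by the Rayleigh factor 0.655
  (single-image NEMA practice, switchable);
- Uniformity = (max − min)/(max + min) × 100 %;
- Spatial linearity = (d_measured − d_actual)/d_actual × 100 % along the
  eight compass directions through a 45-hole, 25 mm grid;
- Slice profile (FWHM and equivalent-width integral) from an opposing
  wedge pair; pixel size as the FWHM of the line-spread function across
  a block edge; central-frequency deviation against f₀ = γB₀ with
  γ = 42.577478518 MHz/T.

**3D geometric distortion**: marker detection (Otsu threshold, 3D
connected components, sub-voxel intensity centroids, optional rigid
setup-error removal) on a 7-plate, 1932-marker fiducial phantom
(25 mm in-plane / 55 mm inter-plate spacing), with the maximum
|measured − known| reported per diameter of spherical volume (DSV 20,
30, 40, 50 cm against tolerances 1, 2, 4, 20 mm).

**B0/B1 field mapping over gantry angles**: dual-echo phase-difference
B0 (f = Δφ/(2πΔTE), in Hz and ppm of f₀), dual-TR B1 via
α = arccos((rn − 1)/(n − r)) with r = S(TR₂)/S(TR₁), n = TR₂/TR₁;
per-angle peak-to-peak B0 inside a 35 cm region with and without
mean-map subtraction, mean |B1 − 100 %| per angle, and the worst-case
displacement estimate ΔB₀/G_read.

**Quantitative MRI**: variable-flip-angle T1 through the linearization
S/sin α = E₁·S/tan α + S₀(1 − E₁) with T1 = −TR/ln E₁; multi-echo
spin-echo T2 and mono-exponential ADC by log-linear least squares (the
dummy echo is discarded by default); the two-root Ernst-angle
flip-angle optimizer (signal fraction 0.71); per-vial bias
B = (measured − nominal)/nominal × 100 % and reproducibility
COV = σ/μ × 100 % across sessions, with Spearman rank tests (exact
permutation p for n ≤ 8) of their dependence on the measured value.

**QA reporting**: tolerance evaluation with the printed operator
semantics (strict `<`/`>`, inclusive intervals), longitudinal OLS trend
with annualized slope, CUSUM change-point flagging, deterministic JSON
reports and CSV logs.

## Worked example

Simulate the fiducial phantom under a radial cubic distortion field
reaching 3.1 mm at r = 250 mm, with Rician noise, and summarize by DSV:

```r
library(mrlqa)

truth <- groundTruth(distortionFieldMm = radialCubicField(3.1 / 250^3),
                     noiseSd = 2, seed = 42L)
gen <- generateFiducialVolume(truth = truth)
markers <- detectMarkers(gen$volume, knownPositions(gen$markers))
summarizeByDsv(markers)
#> DSV distortion summary:
#>  dsv_cm max_distortion_mm n_markers tolerance_mm pass
#>      20         0.3181041       116            1 TRUE
#>      30         0.8652918       408            2 TRUE
#>      40         1.8479554      1000            4 TRUE
#>      50         3.2338159      1684           20 TRUE
```

All 1932 markers are detected and paired; the maximum distortion grows
toward the phantom edge exactly as the imposed r³ field dictates (the
slight excess over the analytic 3.1 mm at DSV 50 is the extreme-value
effect of centroid noise), and each sphere passes its tolerance.

Flip-angle design for T1 mapping at TR = 20 ms over the
1000–2000 ms range, and the worst-case B0 displacement at the maximum
gradient strength:

```r
round(optimalVfaAngles(c(1000, 2000), trMs = 20), 2)
#>  lowDeg highDeg
#>    3.90   22.18     # acquire at {4, 22} degrees
b0DistortionEstimate(3, 1.5, 15)
#> [1] 0.3             # mm, for 3 ppm at 1.5 T read at 15 mT/m
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mrlqa.R simulate --phantom fiducial3d --seed 1 --out sim/
Rscript inst/cli/mrlqa.R distortion --volume sim/fiducial3d.nii --out dsv.json
```

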