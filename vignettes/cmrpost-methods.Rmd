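---
title: "Quantitative methods in cmrpost"
author: "cmrpost authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods in cmrpost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrpost)
```

cmrpost implements the standard quantitative post-processing chain for
cardiovascular MR from operator-supplied contours: chamber volumetry and
mass, semi-quantitative first-pass perfusion, late gadolinium enhancement
(LGE) quantification, T2-weighted edema ratios, T2\* iron relaxometry,
phase-contrast flow, and MR-angiography measurement primitives.  This
vignette documents the models, the tunable parameters and the numerical
choices, and what the synthetic phantoms do and do not establish.

## Coordinate and contour conventions

Contours are closed simple polygons in mm; pixel centers sit at integer
multiples of the pixel spacing, matrix rows index y and columns x; angles
are degrees counterclockwise from +x; slice 0 is the most basal slice.
Areas use the shoelace formula on the polygon vertices; masks are obtained
by a pixel-center-in-polygon test.  No single choice of these conventions
is universal across analysis software, so they are fixed here and used
consistently.

## Ventricular volumetry

Volumes are Simpson slice summations: cross-sectional area times
(slice thickness + interslice gap), summed over contoured slices, with the
same step at the stack ends (the uniform-step rule mirrors the mass
formula; halving the end steps is a possible alternative the package does
not use).  End-diastole and end-systole are single global phases — the
argmax/argmin of the summed blood volume — with ties broken toward the
earlier phase for determinism.  A caller-supplied ES override (e.g. from
aortic valve closure, which contours alone cannot determine) is accepted
and recorded.

The basal-descent rule is stated visually in clinical practice; the
operational form used here is: a basal slice is excluded as atrium when
less than 50% of its endocardial perimeter lies adjacent to myocardium
(within 3 mm of the epicardial contour, both thresholds configurable) *and*
its cavity area expands from ED to ES.  Myocardium without a discernible
cavity contributes to mass only.

LV mass is (epicardial volume − endocardial volume) × 1.05 g/ml.  The
papillary mode — counted as blood (common practice) or as myocardium — is
an explicit argument, carried into every result and report, and moves
tissue conservatively: blood volume and mass change by equal and opposite
amounts times the density.  RV mass is deliberately *not computed*; the
result carries an explicit marker rather than a zero.

Area-length volumes use V = 0.85 A²/L (single plane) and
V = 0.85 A₁A₂/L (biplane).  On an exact ellipse the single-plane formula
exceeds the analytic prolate-spheroid volume by the coefficient ratio
0.85/(8/3π) ≈ 1.0014, which the tests verify.

## AHA segmentation

Slices carrying myocardium are split basal→apex into thirds; remainder
slices go to the basal ring first, then the mid ring (standard practice
names no slice-to-ring rule, so one is fixed and documented).  Segment 1 is
the basal anterior segment; numbering proceeds counterclockwise viewed from
the apex; the anterior RV insertion point — a per-slice *input*, never
inferred — anchors the angular origin.  Boundary angles belong to the
counterclockwise-following segment (half-open spans), so assignment is
total and deterministic.  Transmural chords (default 100 per slice, <1%
quantization on synthetic annuli) run from the endocardial to the
epicardial boundary at equal angular increments from the epicardial
centroid; a chord's enhanced fraction is estimated by 200-point sampling,
normalized by the samples that land on myocardial pixels so that full
enhancement is exactly 1.  Endo/epicardial layers split each pixel by
nearest-boundary transmural depth d_endo/(d_endo+d_epi) < 50%.

## First-pass perfusion

Per-segment (optionally per-layer) mean SI curves are extracted from the
registered dynamic series (no registration is performed; a rigid hook can
be added upstream), with papillary and fat exclusions removed and empty
segments flagged rather than dropped.  Features: baseline = mean of the
first n baseline frames (default 5); contrast arrival = first frame above
baseline + 2 SD(baseline), required to hold for 2 consecutive frames —
clinical practice has no single operational arrival rule, and the two-frame
confirmation suppresses single-frame noise triggers; maximal upslope =
the largest least-squares slope over any 5-frame window (minimum 3,
exhaustive search, reproducibility over speed) between arrival and peak;
upslope integral = trapezoid of SI − baseline from arrival to peak (the
unbounded "area under the curve" needs limits; these are configurable);
MPRI = ratio of stress to rest blood-pool-normalized upslopes.

The defect/artifact classifier encodes the standard reading criteria as a
decision table over per-segment evidence.  Hypoenhancement is detected
where the endocardial-layer SI falls below 0.75 × the ring median at the
same frame (the same factor the width rule uses; no standard pixel-level
threshold exists, so this is a package choice).  An
*inducible defect* begins at/after myocardial contrast arrival, persists
more than 4 RR intervals beyond peak enhancement, is wider than one pixel
(longest contiguous radial run of subthreshold pixels), never dips below
baseline, and is present at stress only.  A *dark-banding artifact* begins
at LV blood-pool arrival before myocardial arrival, lasts under 6 RR,
is about one pixel wide, dips below baseline, and aligns with the
phase-encode direction (segment center within 45° of the axis).  Matched
stress/rest hypoenhancement with LGE in the segment is reported normal
with a scar-match note; stress-only banding alone is never called a
defect; everything else is indeterminate.  Every finding carries its
criteria vector for audit.

## LGE quantification

n-SD masks threshold at remote mean + n·SD (strict >), with recommended
starting points n = 5 for infarction and n = 3 for myocarditis; remote
statistics are per-slice with a pooled option.  FWHM masks threshold at
half the maximum SI inside the operator's scar-core ROI (≥, so the
maximal pixel is always in its own mask); an all-uniform myocardium
triggers a suspicious-uniform warning because the outcome is forced.  An
optional variant threshold 0.5 × (core max + remote mean) exists but is
off by default, since the plain half-maximum assumes a bright core.
No-reflow cores — hypoenhanced regions fully enclosed in-plane by
enhancement — are added by 2D hole filling (idempotent, growth-only).
LGE mass is enhanced area × (thickness + gap) × 1.05 g/ml; per-segment
transmural extent is the mean chord enhanced fraction, binned into
0% / 1–25% / 26–50% / 51–75% / 76–100%, with "0%" reserved for exactly
zero.  Windowing, TI-selection and pattern-reading guidance are reporting
checklist items, not computations.

## T2-weighted edema ratios

The global or regional ratio divides myocardial mean SI by the mean of a
large skeletal-muscle ROI close to the heart.  The classification cutoff
defaults to 1.9 (dark-blood triple-IR; a locally established value is
preferred and its provenance is recorded); the pixel map flags ratios of
2 or higher.  The two cutoffs are deliberately kept as separate
parameters.  Both comparisons are inclusive at the boundary.  Surface-coil
inhomogeneity correction belongs to acquisition and is not attempted.

## T2\* relaxometry

The septal ROI mean per echo is fitted with SI(TE) = S₀·exp(−TE/T2\*)
by Levenberg–Marquardt least squares, initialized from the log-linear
regression, T2\* bounded to (0, 1000] ms, fixed tolerances — the fit is
deterministic given the data.  No constant offset term is fitted: the
model is the pure mono-exponential, with truncation as the plateau remedy.
The truncation method drops the latest echo while the fit R² stays below
0.999 and more than 3 points remain.  The 0.999 default was chosen from
the phantom behaviour of the estimator itself: a clean mono-exponential
fits to R² ≈ 1 − 10⁻⁹ (so clean curves are never truncated), while a
noise-floor plateau at 5% of S₀ holds the full 8-echo fit near R² ≈ 0.997
— high enough that a looser common choice such as 0.995 would never
engage, leaving the plateau bias (≈ +6% at T2\* = 5 ms) uncorrected.
Black-blood acquisitions show little plateau, so a metadata flag defaults
truncation off for them.  Classification at 1.5 T: < 10 ms high risk,
10–20 ms overload, ≥ 20 ms no overload, normal reference 40 ms; 3 T input
is rejected rather than mis-scaled.

## Phase-contrast flow

Velocities live in a window of width 2·VENC.  Aliased values are recovered
by re-expressing each velocity as v + 2·VENC·k inside a shifted window
(the worked example: a true 175 cm/s recorded as −125 cm/s at VENC 150 is
restored by the window (−100, +200)).  Background offsets are corrected
either by a per-frame first-order 2D polynomial fitted to stationary
tissue (exact for planar offsets) or by subtracting a static phantom's
per-pixel mean.  Flux integrates ROI pixel velocity × pixel area per
frame; antegrade/retrograde volumes are trapezoidal time integrals of the
positive/negative flux with the last interval closing the RR cycle (the
choice of integration rule is open; the trapezoid is standard and makes
net = antegrade − retrograde exact).  The antegrade direction is a
declared input, since image orientation alone is ambiguous.  Derived
values follow their printed formulas (RF, CO, CI, lung split, AV
regurgitation methods A and B).  Peak velocity is reported either as the
single-pixel maximum or as the maximum 3×3 neighborhood mean (clipped to
the ROI); the mode is recorded because interpretation depends on it.  QC
flags: TE > 3.5 ms, ≥3 ROI pixels within 2% of the window edge (suspected
aliasing), and a peak under 40% of VENC (poor velocity contrast).

## MR angiography

Subtraction is voxelwise; MIP is the per-ray maximum.  The "widest inner
diameter" is computed as the maximal caliper width — the diameter of the
convex hull of the lumen cross-section, which must be taken perpendicular
to the vessel axis by the caller.  The aortic report is a fixed nine-level
table; sinus and sinotubular-junction rows are suppressed on ungated data,
and all three sinus-commissure dimensions are accepted at level 1.

## The phantoms: what they emulate and what they do not

The generators produce every input the analysis modules consume, with
truth computed from the generating parameters only (never by the code
under test), and are bit-reproducible from (scenario, seed).

* **Ellipsoid ventricle** — elliptical sections of an analytic ellipsoid
  with a uniform shell; truth from 4/3·π·abc.  Default dimensions
  (ED semi-axes 25/25/45 mm, wall 8 mm, 8 mm slices with 2 mm gap,
  12 phases) give normal-range adult volumes.
* **Perfusion** — gamma-variate first-pass curves on a 49×49, 40-frame
  series at one frame per RR; blood-pool time-to-peak 7 RR so the bolus
  upslope spans the default 5-frame analysis window (a shorter rise makes
  the window estimator sensitive to one-frame arrival jitter); stress/rest
  amplitude ratio 2; defects are stress-only subendocardial amplitude
  reductions, artifacts one-pixel transient bands at blood-pool arrival,
  dark (below baseline) and phase-encode aligned.  Noise is Gaussian;
  SNR 50 at peak myocardial SI in the recovery checks.
* **LGE** — Gaussian remote myocardium (mean 100, SD 10), lesion at
  SI 400 with a stated transmural fraction, optional enclosed dark core.
  The default lesion sector (10–110°) deliberately avoids AHA segment
  boundaries: a lesion edge exactly on a boundary bleeds a fraction of a
  pixel into the neighbouring segment's chords, which the exact-zero bin
  would surface as "1–25%".
* **T2\*** — SI(TE) = √((S₀e^(−TE/T2\*))² + floor²) with per-pixel Rician
  noise, 8 echoes at 2–16 ms.
* **Flow** — circular vessel, uniform or parabolic profile (mean =
  peak/2), systolic pulse waveform with mild diastolic reversal, optional
  wrap-around aliasing and planar offset; Gaussian velocity noise.

What passing these tests shows: the estimators implement their stated
formulas exactly, converge on analytic geometry, and are robust to the
modelled noise at the stated levels.  What they do not show: behaviour
under real-world motion, registration error, surface-coil shading,
arrhythmia, partial-volume at oblique wall orientations, or vendor
reconstruction differences — none of which the phantoms model.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the sphere phantom at
10/5/2.5 mm slices, 100 perfusion seeds for the classifier sweep and 10
for MPRI recovery, 200 Monte-Carlo replicates for the T2\* comparisons,
and single phantoms elsewhere; these sizes give stable statistics for
every asserted margin while keeping a full run in well under a minute of
compute per module.

## Known limitations

Automatic contour detection, absolute myocardial blood flow, peri-infarct
grey zone, T1/T2 mapping, strain, 4D flow, volume rendering and 3 T iron
calibration are out of scope.  DICOM parsing is not included: the package
reads NIfTI plus its JSON contour-exchange format, and records the
declared compression state of the source data (warning on lossy).  The RV
insertion point and the antegrade flow direction are inputs; the package
never guesses either.
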