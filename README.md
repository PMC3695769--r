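# cmrpost

Quantitative post-processing for cardiovascular MR (CMR) studies, for
imaging scientists and analysis-pipeline developers who have contours and
image series in hand and need the standard numbers computed the standard
way: bi-ventricular volumetry, LV mass, first-pass perfusion indices with a
rule-based defect/artifact classifier, late gadolinium enhancement (LGE)
quantification, T2-weighted edema ratios, T2\* iron relaxometry,
phase-contrast flow, and MR-angiography measurements.  A synthetic phantom
generator produces every input with analytic ground truth, so the whole
pipeline is testable without clinical data.

## The quantities at the core

* **Volumetry** — Simpson summation V = Σᵢ Aᵢ·(Δz + gap) over short-axis
  slices, with global ED/ES phase selection, basal-descent handling and an
  explicit papillary-muscle mode; LV mass = (V_epi − V_endo) × 1.05 g/ml;
  area-length volumes V = 0.85·A²/L and V = 0.85·A₁A₂/L.
* **Perfusion** — per-AHA-segment SI(t) curves; maximal upslope (windowed
  least squares), time to peak, upslope integral; MPRI =
  (upslope_myo/upslope_LV)_stress / (upslope_myo/upslope_LV)_rest; a
  decision table separating inducible defects (>1 pixel wide, persisting
  >4 RR beyond peak, stress-only, never below baseline) from dark-banding
  artifacts (~1 pixel, transient <6 RR, below baseline, phase-encode
  aligned, at blood-pool arrival).
* **LGE** — thresholds at remote mean + n·SD (n = 5 infarction, 3
  myocarditis) or half the scar-core maximum (FWHM); no-reflow hole
  filling; mass = area·(Δz+gap)·1.05 g/ml; transmurality in the five bins
  0 / 1–25 / 26–50 / 51–75 / 76–100 %.
* **T2w** — SI(myocardium)/SI(skeletal muscle), cutoff 1.9; pixel map at
  ratio ≥ 2.
* **T2\*** — SI(TE) = S₀e^(−TE/T2\*) by Levenberg–Marquardt with echo
  truncation against the noise-floor plateau; 1.5 T classification at
  20 ms (overload) and 10 ms (high risk), normal 40 ms.
* **Flow** — Q(t) = Σ v·dA over the lumen; antegrade/retrograde trapezoid
  integrals; RF = 100·retro/ante; CO = net·HR/1000; VENC window shifting
  v → v + 2·VENC·k to undo aliasing; planar background-offset correction.

## Worked example

```r
library(cmrpost)

# a cycling ellipsoidal ventricle with known truth
ph <- ellipsoid_ventricle_stack()
lv <- lv_assessment(ph$stack)
lv
#> LV volumetry (simpson_stack, papillary included_in_blood)
#>   EDV 118.5 ml  ESV 54.8 ml  SV 63.7 ml  EF 53.8%
#>   CO 4.46 L/min
#>   mass 113.3 g
ph$truth$ef_pct    # 53.76 — generator truth, matched within discretization
ph$truth$mass_g    # 113.32

# T2* iron assessment on a multi-echo phantom
t2 <- t2star_series(seed = 3, t2star_ms = 15, noise_floor = 30, rician_sd = 10)
fit <- truncation_fit(t2$curve)
fit
#> T2* 15.03 ms (S0 1001.0, R^2 1.0000, 8 points)
classify_iron(fit$t2star_ms)$classification
#> [1] "overload"
```

EDV here is the Simpson sum over the contoured slices (118.5 ml vs the
analytic 117.8 ml, a 0.6% discretization difference); EF and mass agree
with the generator's closed-form truth, and mass/wall-volume is exactly
1.05 g/ml by construction of the mass formula.

A thin command-line interface wraps the same functions
(`system.file("cli", "cmrpost.R", package = "cmrpost")`), with subcommands
`volumetry`, `perfusion`, `lge`, `t2ratio`, `t2star`, `flow`, `mra` and
`phantom` operating on NIfTI images and the package's JSON contour format
(schema in `inst/extdata/contour-schema.json`).

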