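Package: cmrpost
Title: Standardized Quantitative Post-Processing for Cardiovascular MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standardized quantitative post-processing for cardiovascular
    magnetic resonance studies: bi-ventricular volumetry by Simpson slice
    summation, left-ventricular mass, area-length volumes, semi-quantitative
    first-pass perfusion with a rule-based defect/artifact classifier, late
    gadolinium enhancement quantification by n-SD and full-width-half-maximum
    thresholding with transmurality categories, T2-weighted edema ratios,
    T2* iron relaxometry with echo truncation, phase-contrast flow
    quantification with velocity-aliasing and background-offset correction,
    and MR angiography measurement primitives.  A synthetic phantom generator
    produces every input with analytic ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    minpack.lm,
    EBImage,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
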