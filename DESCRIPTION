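Package: fllalign
Title: Photometric Assessment of Frontal Lower-Limb Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based measurement of frontal-plane lower-limb alignment
    from anterior-view photographs and full-length radiographs: computes the
    pelvis-knee-ankle (PKA), hip-knee-ankle (HKA) and femoral mechanical-vs-
    topographic axis (FMA-FTA) angles from digitized 2D landmarks, converts
    photographic PKA to an estimated radiographic HKA through a linear
    calibration, and provides the full method-comparison battery: two-way
    random-effects absolute-agreement intraclass correlation ICC(2,k) with
    McGraw-Wong confidence intervals, Bland-Altman limits of agreement,
    Pearson correlation and ordinary least-squares regression with the
    standard error of the estimate. A synthetic limb-and-rater simulator with
    known ground-truth alignment supports accuracy and reliability studies
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
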