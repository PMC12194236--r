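---
title: "Photometric assessment of frontal lower-limb alignment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photometric assessment of frontal lower-limb alignment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fllalign)
```

## The measurement problem

Frontal-plane lower-limb alignment (varus/valgus) is conventionally measured
on a weight-bearing full-length radiograph as the hip–knee–ankle angle (HKA):
the medial angle between the femoral mechanical axis (femoral head centre to
femoral notch centre) and the tibial mechanical axis (tibial eminence centre
to ankle articular centre). A straight limb measures 180°; values below 180°
are varus, above 180° valgus.

Radiography carries radiation dose and cost. The photometric alternative
implemented here replaces the (impalpable) femoral head with the easily
palpable anterior superior iliac spine (ASIS): on an anterior-view
photograph, the femoral *topographic* axis runs from the ASIS to the knee
centre (midpoint of skin markers on the distal femoral condyle borders), the
tibial topographic axis from the knee centre to the ankle centre (midpoint of
the malleolus markers), and their medial angle is the pelvis–knee–ankle angle
(PKA). Because the ASIS lies lateral and proximal to the hip centre, the PKA
is systematically more valgus than the HKA; the offset between the femoral
mechanical and topographic axes (the FMA–FTA angle, measured on the
radiograph) is the anatomical source of most of that discrepancy. A linear
calibration maps PKA to an estimated HKA.

## Geometry

All angle computation happens in a *limb-local frame*: +x medial for the limb
under measurement, +y superior. `to_limb_frame()` is the only place where
image (raster) coordinates, side, and pixel scale enter; for a right limb in
an anterior view, medial is image-right, so x is kept and y negated, and for
a left limb x is negated as well. This makes the varus sign rule
side-independent, which the tests exercise as a mirror-symmetry invariant.

The kernel is the signed counter-clockwise rotation ψ taking the proximal
axis direction onto the distal one, computed as `atan2(cross, dot)` — stable
for the near-parallel axes that dominate clinical data. PKA and HKA are
`180° − ψ`, so a tibial axis rotated laterally (varus) gives an angle below
180°. The FMA–FTA angle is reported unsigned in [0°, 90°): clinically it is
quoted as a magnitude, and its direction is already encoded in the PKA–HKA
difference. Angles are invariant under translation, rotation and uniform
scaling of the landmark configuration, and the suite verifies recovery of
planned deviations against an explicit rotation-matrix oracle to 1e-9° over
a ±15° grid.

Degenerate inputs (coincident required landmarks, a zero-length axis) raise
errors rather than producing angles: a measurement method must not fabricate
values. The neutral band of `classify_alignment()` defaults to exact
equality with 180° and is configurable, since no clinical consensus band
exists.

## The statistical battery

`icc2k()` implements the two-way random-effects, absolute-agreement,
average-measures intraclass correlation — ICC(A,k) in McGraw & Wong's
taxonomy — from the unreplicated two-way ANOVA decomposition:

* estimate: `(MSR − MSE) / (MSR + (MSC − MSE)/n)`;
* confidence interval: the McGraw–Wong single-measure bounds with a
  Satterthwaite-approximated denominator degrees of freedom, stepped up to
  average measures by the Spearman–Brown relation.

Absolute agreement (not consistency) is the right form here because a rater
with a constant offset *should* be penalised. A constant matrix has no
defined ICC and raises an error instead of returning NaN. Interpretation
uses the Koo–Li bands (<0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, >0.9
excellent), with boundary values assigned to the lower-adjacent band's upper
label. In degenerate samples the point estimate can exceed 1 (negative
variance components); the estimate is reported as computed and only the band
label clamps.

`bland_altman()` uses the sample (n−1) standard deviation and a default
multiplier of 1.96, which exactly reproduces published limits from a
published bias and SD; a t-quantile multiplier can be supplied instead. The
accuracy pipeline orients differences as HKA − PKA, so the systematically
more-varus radiographic angle yields a negative bias. `pearson_r()` and
`ols_fit()` are closed-form implementations (the t transform for the
p-value; normal equations, `R² = 1 − SSE/SST`, `SEE = √(SSE/(n−2))`), tested
against base R's `cor.test`/`lm` and an independent matrix solve on random
instances — the base routines serve as oracles, not as the implementation.

## Calibration

`published_calibration()` ships the reference mapping
`HKA = −10.54 + 1.0364 · PKA` (SEE 1.2427°, from 33 limbs of 17 patients,
one rater) so an estimated HKA is available without any radiograph.
`fit_calibration()` refits the line on local paired data, which is
preferable whenever radiographs exist. Predictions outside (90°, 270°) are
flagged as extrapolation. Single predictions are reported alongside the SEE;
full prediction intervals are out of scope.

## The synthetic cohort

No raw study data are deposited, so the package carries a generator that
emulates the two study designs with known ground truth.

Each subject is a planar skeleton: femoral head above the knee, tibial axis
rotated off the femoral axis by the drawn deviation `180° − HKA`, ASIS
placed lateral/proximal so the FMA–FTA angle matches its draw, and
photographic surface landmarks (condyle and malleolus marker pairs, 90 and
70 mm spans; femur 430 mm, tibia 380 mm — adult averages) placed so that the
noise-free PKA equals `HKA + FMA–FTA + ankle-centre offset`. The geometry
module applied to a zero-noise rendering returns the configured angles to
1e-9°, so all noise propagates through the same code path under test.

Population presets:

* **orthopedic**: true HKA ~ N(178.8°, 5.2°), the patient group.
* **healthy**: noise-free PKA targeted at N(182.6°, 2.5°); the HKA moments
  are solved from that target (mean 178.7°, SD ≈ 2.75°) given the
  discrepancy model below.
* FMA–FTA ~ N(3.1°, 1.0°) truncated at zero; ankle-centre offset
  ~ N(0.8°, 0.3°), chosen so the mean photo–radio discrepancy is 3.9°.

**Alignment coupling.** A purely additive, independent discrepancy would
make the PKA variance strictly larger than the HKA variance and attenuate
the HKA-on-PKA regression slope to ≈0.955 — contradicting both the near-unit
clinical slope and the observation that measured PKA spreads are *smaller*
than HKA spreads. The generator therefore couples the discrepancy to
alignment: its conditional mean shifts by `−γ(HKA − μ)`, with γ solved from
the configured variances so the population regression slope is exactly 1
(`γ(1−γ) = var(discrepancy)/var(HKA)`; γ ≈ 0.042 orthopedic, 0.174
healthy). The residual trade-off is a noise-free orthopedic PKA SD of ≈5.1°
rather than the reported 4.8°.

**Noise model.** Noise acts on landmark coordinates in millimetres, never on
angles directly: per-marking isotropic digitization noise (default SD
1.5 mm, fresh per reading), a per-rater systematic shift per landmark
(SD 1.5 mm, constant across subjects and sessions), and a between-photograph
stance change modelled as a rotation of the tibial segment about the knee
centre (SD 0.5°). A rigid rotation of the *whole* configuration would leave
every inter-axis angle unchanged — angles are rotation-invariant — so the
stance term must act on a segment to produce any test–retest variance. The
three magnitudes are calibrated, not measured: no landmark-level error
magnitudes are published, so they were set once from the published
Bland–Altman limit widths of the reliability table (reading differences of a
few tenths of a degree, between-photograph differences near ±1.3°) and not
revisited.

In the accuracy design the photograph and radiograph share one acquisition,
so no stance term is drawn; and with a single rater, that rater's systematic
shift is statistically unidentifiable from the population offset, so it is
absorbed into the configured FMA–FTA + ankle offset rather than drawn. Both
choices keep the generating bias recoverable (±0.1° at n = 2000, which the
suite checks).

Randomness is a single master seed with hierarchical substreams keyed by
(subject, side, session, rater, reading), so identical configs are
bit-reproducible and adding raters never perturbs subject draws.

**What the generator does not emulate:** out-of-plane limb rotation and
perspective, BMI/soft-tissue-thickness effects on landmark error,
rater-by-subject interactions, bilateral correlation within a subject, and
severity-dependent marking difficulty. Passing tests therefore demonstrate
internal consistency of the method and its statistics under a plausible
error model — not clinical accuracy on real photographs.

## Study pipelines and problem sizes

`run_accuracy_study()` consumes paired angles (or a landmark table) and
reports Pearson r, the calibration regression, Bland–Altman on HKA − PKA,
and group summaries; print rounding (angles 1 decimal, bias/limits 3
decimals, r 2 decimals) never feeds back into computation.
`run_reliability_study()` mirrors the reliability table layout exactly:
three intrarater rows (ICC(2,2) + Bland–Altman of the two readings), one
pooled interrater ICC(2,3) with *pairwise* Bland–Altman rows (no pooled
Bland–Altman and no pairwise ICC are invented), and one test–retest row. The
test–retest matrix stacks each rater's first readings of the two
photographs (subject × rater rows, k = 2).

Default study sizes follow the emulated designs: 33 limbs from 17 subjects
(accuracy; limbs pooled as independent observations, with a
one-limb-per-subject toggle) and 50 subjects × 3 raters × 2 photographs × 2
readings, right limb (reliability). Verification runs use n = 2000 limbs for
parameter recovery and 100 replicate reliability studies, sizes at which
Monte-Carlo error is comfortably below the tested tolerances.

The command-line front end (`cli_entry()`, launcher `inst/cli/flla`) wires
the four steps — simulate, measure, accuracy, reliability — over CSV and
JSON, with deterministic outputs under a fixed seed and a provenance block
(package version, seed, config hash) in every report.

## Known limitations

The calibration is a single pooled line: no stratification by sex, age,
side, or deformity severity. The ICC machinery covers the ICC(2,1)/(2,k)
family only, and the Bland–Altman analysis assumes one pair per subject
(no repeated-measures variance correction). The generator's noise magnitudes
are calibrated to reproduce the reliability table's order of magnitude, so
agreement statistics computed on synthetic data validate the machinery, not
the field performance of the photometric method.
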