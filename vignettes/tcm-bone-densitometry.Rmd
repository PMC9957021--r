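---
title: "Two-compartment CT bone densitometry: models, simulation design, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment CT bone densitometry: models, simulation design, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmbmd)
```

## The two-compartment model

A CT number is attenuation relative to water,
$CT = 1000\,(\bar\mu/\tilde\mu_w - 1)$, with both attenuations weighted by
the X-ray spectrum. Modelling trabecular bone as a volume mixture of a
cortical-bone-equivalent compartment (1.0 g/cm³ K₂HPO₄ solution) and a
marrow-equivalent compartment (water), the mixture CT number is linear in
the bone volume fraction, so the fraction is recovered from three CT
numbers measured under the *same* spectrum:

$$BVF = \frac{CT_{tra} - CT_{mar}}{CT_{cor} - CT_{mar}},
\qquad vBMD = BVF \times \rho_{cor}.$$

Two assumptions carry the method:

* **Water is a fair marrow surrogate.** Marrow mixes adipose tissue
  (≈ −80 to −100 HU) and soft tissue (≈ 50–70 HU); their average CT value
  and effective atomic number are close to water's, so both the magnitude
  and the energy dependence of the substitution error are small.
* **The spectrum cancels.** Numerator and denominator of the BVF ratio are
  differences of CT numbers measured under one spectrum, so the
  energy-dependent scale drops out. This is exact under the additive-salt
  solution model used by the simulator (below), and is the reason vBMD
  thresholds transfer across tube voltages while raw HU thresholds do not.

`rho_cortical` defaults to 1 g/cm³, the density of the cortical-equivalent
reference solution: phantom "theoretical vBMD" then *equals* the K₂HPO₄
concentration and the validation experiment can be read against the
identity line. Users who want a physiological cortical density can set
0.884 g/cm³ (population mean cortical density; the same choice scales every
vBMD in a cohort by a constant, leaving ROC analyses untouched). BVF is
deliberately **not clamped** to [0, 1] by default: slightly negative values
in near-pure-marrow voxels are evidence about noise levels and calibration
quality, and clamping would bias ROI means near the edges of the
calibration span. `measure_vbmd(..., clamp = TRUE)` clamps and flags.

## The phantom simulator

The validation instrument is a digital ten-compartment phantom: water plus
nine K₂HPO₄ solutions from 0.02 to 1.5 g/cm³, each compartment
30 × 15 × 15 mm, rendered at 0.5 mm isotropic voxels (54 000 voxels per
compartment) inside a water background. The physical phantom it emulates
has five compartments filled twice; one volume with all ten solutions is
equivalent because only compartment-mean CT numbers are consumed.

Material physics uses a two-basis parameterization of the mass attenuation
per element over 10–150 keV: photoelectric $\propto Z^{4.6} E^{-3}$ per
gram plus the Klein–Nishina incoherent cross-section per electron. The one
free constant is anchored to aluminum at 30 keV (1.128 cm²/g), which puts
water within 3% of its reference value at 60 keV. Absolute accuracy is not
the point — the TCM ratio cancels the scale — but the parameterization
gives the qualitatively correct behaviour the validation needs: attenuation
monotonically decreasing with energy, salt solutions hardening-sensitive
through the photoelectric term, and therefore compartment HU that *do*
change between 100 and 120 kVp while measured vBMD does not.

Solutions follow an additive-salt model,
$\mu_{sol}(E) = \mu_w(E) + c\, (\mu/\rho)_{salt}(E)$, ignoring water
displacement by the dissolved salt. That keeps theoretical vBMD identical
to concentration — the same convention under which calibration phantoms
equate the two — and makes the energy cancellation exact, which is a
fidelity limit worth stating: a real solution displaces water, so a real
phantom shows sub-percent deviations from the identity line that this
simulator will not reproduce.

Spectra are filtered Kramers continua (weights ∝ kVp − E on a 1 keV grid,
2.5 mm Al filtration, no characteristic lines); noise is i.i.d. Gaussian
per voxel with a default SD of 10 HU. Streaks, scatter, beam hardening and
detector models are out of scope — with ROI means over ≥ 10⁴ voxels the
mean-HU sampling error is ≈ 0.04 HU, far below any of those structured
effects would need to be to matter at the 0.5% accuracy level being
checked. Consequently, a passing phantom validation here demonstrates the
*algebra* of the method (exact inversion, energy cancellation, noise
propagation), not robustness to reconstruction artifacts.

## ROI protocol

ROIs are explicit, reproducible annotation files rather than interactive
drawings: per vertebra an axial index range for the vertebral body and an
ellipse (center and semi-axes, 0-based voxel coordinates). The measured
slice is the median of the range (lower-middle on even lengths — a fixed
tie rule so annotations are portable), and a voxel belongs to the ROI when
its *center* is inside the ellipse. The center test, rather than
partial-volume weighting, makes the measurement deterministic and
oracle-checkable; the ROI sizes in question (hundreds of voxels) make the
rim contribution negligible against the trabecular mean. DICOM series
reading is not built in — no R DICOM reader is part of this package's
dependency set — but the mandatory rescale arithmetic is exposed as
`hu_rescale()` and NIfTI volumes (to which series convert losslessly) are
read natively.

## ROC conventions

The screening polarity is fixed: a subject tests positive when vBMD is at
or below the threshold, matching how the clinical cutoffs are printed
("≤ 0.116 g/cm³"). Candidate thresholds are midpoints between consecutive
sorted unique scores plus one sentinel on either end, so each achievable
confusion matrix appears exactly once and tied scores move as a block; the
trapezoid AUC over that curve equals the Mann–Whitney concordance
probability with ties counted ½ (asserted against an exhaustive
pair-enumeration oracle in the tests). The Youden point maximizes
$J = sens + spec - 1$; ties break toward higher sensitivity (screening
prefers catching disease), then toward the lower threshold. With perfectly
separated classes the returned threshold is the midpoint of the class gap.

The "average" predictor is the per-subject mean vBMD over available
vertebrae, treated as a fifth classifier — not the mean of the four
per-vertebra thresholds, which is the only reading under which the
published average rows form a self-consistent classifier. The osteopenia
endpoint pools osteopenia and osteoporosis subjects as positives against
normal controls. Percentages are rounded to one decimal half away from
zero, thresholds to three decimals; no multiple-testing correction is
applied anywhere, matching the source analysis. `validate_tables()`
re-derives every published accuracy cell from its own printed
sensitivity/specificity and group sizes: sixteen of twenty cells
reconstruct exactly; the four experimental osteopenia cells L2–L4 and
"average" do not, under any integral confusion matrix, and are flagged
rather than hidden.

## The synthetic cohort generator

Patient data are not redistributable, so the cohort pipeline is exercised
on a generator that reproduces the *structure* of the screening study:
three groups (normal/osteopenia/osteoporosis) of 57/25/23 subjects
(experimental preset; 43/18/14 for the test preset) with the published sex
ratios and age distributions; per-vertebra vBMD around group means
0.175/0.115/0.062 g/cm³ (residual SDs 0.03/0.02/0.015, 60% of the variance
shared across a subject's vertebrae); aBMD through a linear link
(intercept 0.68 g/cm², slope 3.2 g/cm² per g/cm³); and per-vertebra
T-scores against young-adult references back-derived from the published
per-group aBMD and T-score tables (means 1.184/1.149/1.099/1.080 g/cm²,
SDs 0.113/0.101/0.101/0.107). All of it is configuration, none of it
hard-coded.

Two design points deserve their own paragraphs, because the obvious
alternatives are quietly inconsistent.

**The age slope is attenuated inside groups.** The marginal decline rates
(−0.005 g/cm³ per year for women, −0.0031 for men) cannot be injected at
full strength *within* each diagnostic group: group membership is itself an
age-correlated selection (older subjects are osteoporotic), so the pooled
per-sex regression would see the within-group slope *plus* the
between-group composition effect and return roughly −0.007 for women.
Worse, a full-strength within-group slope drives the osteoporosis group
mean negative at its average age of 64.6. The generator therefore centers
the age trend at each group's mean age (so configured group means are the
realized group means) and attenuates it by a factor of 0.85 inside groups,
calibrated so that the between-group composition supplies exactly the
remainder: the pooled per-sex OLS on generated cohorts returns the
configured marginal slopes within estimation error, at n = 105 and n = 500.

**Link noise is a rare-discordance mixture.** The moderate clinical
vBMD–aBMD correlation (r ≈ 0.65–0.72) cannot come from homoscedastic
Gaussian link noise: the noise SD required (≈ 0.2 g/cm²) is comparable to
the whole inter-group aBMD span and would randomize the T-score labels.
Clinically, discordance is concentrated in a minority of subjects whose
aBMD is inflated by degenerative change, osteophytes or unrecognized
fracture. The generator mirrors that: routine subject-level noise of
0.05 g/cm² (plus 0.02 per vertebra), and with probability 0.18 a
discordance offset of 0.32–0.62 g/cm², positive in 80% of cases. Bounded
offsets keep the realized correlation stable across seeds — Monte-Carlo
calibration, done before freezing the defaults, puts all four per-vertebra
correlations inside [0.60, 0.80] for ~90% of experimental-size cohorts —
while leaving four-fifths of subjects with nearly clean labels, which is
what keeps the Youden threshold between the osteoporosis and osteopenia
group means in ≥ 95% of seeds.

**What label concordance this design can and cannot deliver.** The
generative chain is group → vBMD → aBMD → T-score: the derived DXA-style
label sees the group only through vBMD. With within-group vBMD SDs of
0.02–0.06 (age trend included) against group gaps of 0.05–0.06 g/cm³, the
three groups overlap enough that *no* setting of the link noise — including
zero — recovers the generative label for much more than ~65% of subjects;
matching the published per-group aBMD spreads (SD 0.11–0.15 g/cm²) gives
the same ceiling from the other direction. In the real study there is no
such gap because the T-score *defines* the group rather than estimating a
latent one. Concordance between generated labels and generative groups
under the defaults sits near 0.63, far above the 1/3 chance level, with
the extreme groups always modal in their own label; the property tests
assert exactly that, and analyses that need a clean reference standard
should use the `group` column, which is the ground truth.

The generator does **not** emulate: DXA projection physics and BMI effects
on aBMD, per-vertebra vBMD differences (the study found none), non-Gaussian
age distributions, or scanner drift between the phantom and patient scans.
Passing cohort tests therefore validate the statistical machinery
(ROC/Youden/regression/correlation) under a plausible data-generating
process, not the clinical threshold values themselves — which is why the
patient-derived constants (0.116/0.126 g/cm³, AUC 0.930/0.897) ship as
reference data rather than being re-claimed from simulation.

## Numerical choices and problem sizes

* Phantom experiments run at 0.5 mm voxels (54 000-voxel compartment ROIs,
  ≈ 0.9 s per render); unit tests use 1–2 mm voxels where only exactness,
  not noise behaviour, is at stake.
* Noiseless validation recovers concentration to < 10⁻⁹ relative; the
  energy-independence check compares 100 vs 120 kVp at < 10⁻⁶ relative.
* ROC oracle equivalence is asserted on 200 random instances (n ≤ 50, with
  ties) against exhaustive pair enumeration and exhaustive threshold
  search, and cross-checked against an independent ROC implementation.
* Scores feeding ROC are meaningful at ~1 mg/cm³; the midpoint-threshold
  construction assumes distinct doubles are distinguishable, so scores
  separated only by machine epsilon (never produced by real measurements)
  would split spuriously.
* Degenerate inputs error loudly with classed conditions: non-positive
  water attenuation, equal calibration references, swapped references,
  single-class ROC, empty ROIs, constant correlation inputs,
  single-age regression strata.
* Every stochastic routine takes an explicit seed; cohort generation and
  the full pipeline are byte-reproducible per seed.

## Known limitations

The simulator validates algebra and statistics, not image formation:
scatter, beam hardening, partial-volume effects at the ROI rim, and
contrast-enhanced scans are outside the model. The attenuation
parameterization is a two-term fit, not tabulated reference data, so
absolute HU values (e.g. ≈ 3700 HU for the 1.0 g/cm³ solution at 120 kVp)
run higher than a clinical scanner would report even though every
TCM-relevant *relationship* (linearity in concentration, energy
dependence, monotonicity) is preserved. And the synthetic cohort's label
noise, while calibrated to the published correlation band, is one of many
mixtures consistent with it; conclusions that depend on the exact shape of
vBMD–aBMD discordance should not be read off this generator.
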