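---
title: "Methods: PK/PD and plaque-quantification models in amyloidpkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PK/PD and plaque-quantification models in amyloidpkpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidpkpd)
```

This vignette documents the models behind `amyloidpkpd`, the choices
made where a convention had to be fixed, and what the synthetic-data
closed loops do and do not demonstrate. The package covers the analysis
chain of a preclinical BACE-1 inhibitor program: non-compartmental PK
with unbound-exposure scaling, dose–response potency estimation,
indirect-response modelling of CSF amyloid-β suppression, effect-curve
summaries, and brightfield plaque/glia quantification.

## Non-compartmental PK

`auc_trapezoid()` uses the **linear trapezoidal rule only**. Preclinical
sampling of this kind is sparse and the summary quantities of interest
are "approximate areas"; a single quadrature rule keeps every reported
AUC auditable by hand. Window endpoints that fall between samples are
interpolated linearly, which makes AUC exactly additive over adjacent
windows — a property the test suite asserts on random profiles.

**BLQ handling** follows the standard NCA convention: samples below the
LLOQ before the first quantifiable concentration contribute 0; embedded
or trailing BLQ samples contribute LLOQ/2 to the AUC and are excluded
from the terminal regression.

**Terminal phase selection** (`terminal_half_life()`): the last three
quantifiable samples after Tmax, extended one earlier sample at a time
for as long as the adjusted R² of the log-linear regression improves.
The rule is deterministic, printed in the result (`n_points`,
`adj_r2`), and overridable via `n_points`.

**Extrapolation to infinity** uses the regression-predicted last
concentration, `AUC_inf = AUC_0-t + C_last,pred/λ_z`; an extrapolated
fraction above 20 % attaches a warning to the `nca_result` rather than
failing, since truncated designs are common and the user should decide.

Units are kept consistent rather than configurable: doses in µmol/kg
and concentrations in µM make `Dose/AUC` come out in l/h/kg, converted
once to the conventional ml/min/kg at the reporting boundary. All
internal values carry full precision; rounding to printed precision is
left to the caller.

One deliberate non-feature: the terminal volume `Vz = CL/λ_z` is the
only volume reported. Published cross-species tables sometimes print a
steady-state volume instead, and the two are not interconvertible from
CL and t½ alone, so no attempt is made to reproduce such a value.

## Dose–response

`fit_4pl()` fits `y = bottom + (top − bottom)/(1 + (x/mid)^hill)` by
Levenberg–Marquardt with the midpoint parameterized as `log10(mid)` —
the fit lives on the log-dose axis, the natural scale of serial-dilution
designs, and the midpoint stays positive by construction. Standard
errors come from the asymptotic covariance `s²(JᵀJ)⁻¹`; the midpoint SE
is transported from the log scale by the delta method, matching the
"estimate ± SE" convention of potency reporting. Starting values are
`top = max(y)`, `bottom = min(y)`, midpoint at the dose nearest the
half-range response, `|hill| = 1` signed by the observed direction.

`ed50_from_study()` converts treated group means to percent inhibition
of the vehicle mean and fixes `bottom = 0`: with no drug there is no
inhibition, and the vehicle group enters **only** through the
normalization, never as a fitted point — this avoids `log(0)` and keeps
the design honest about what the vehicle arm measures. Degenerate
designs are flagged rather than silently fitted: responses
indistinguishable from vehicle (< 5 % everywhere) raise a "no response"
error; a fitted midpoint outside the tested dose range sets
`unidentifiable = TRUE`, because every observed dose then sits on one
side of the half-maximum.

## Indirect-response (turnover) model

The PD model is **inhibition of production**:

$$\frac{dR}{dt} = k_{in}\left(1 - I_{max}\frac{C(t)}{IC_{50}+C(t)}\right) - k_{out}R,
\qquad R(0)=R_0=k_{in}/k_{out}.$$

A synthesis inhibitor acts on the production arm, so this is the
mechanistically matching structure, and `imax = 1` by default reflects
complete blockade of the enzyme at saturating concentration. The
signature consequence — asserted in the tests — is that the fastest
possible decline of the biomarker is its own clearance,
`R0·e^(−kout·t)`; `complete_blockade_reduction()` is that closed form.
At the rodent CSF Aβ clearance rate of 0.48 h⁻¹ it predicts an 85 %
reduction after 4 h, which is why even a fully suppressive dose cannot
show a deeper acute effect.

**Integration.** `simulate_turnover()` uses `deSolve::lsoda` with
rtol 10⁻⁸/atol 10⁻¹⁰. A measured concentration profile is interpolated
linearly in time; a fitted forcing is evaluated in closed form. The
one-compartment closed form is protected against `ka = ke` by a 10⁻⁹
perturbation.

**Fitting** (`fit_turnover()`) is sequential — PK first, then PD —
mirroring how the data arrive and keeping identifiability analyzable.
The forcing is fitted to pooled blood samples on the log scale
(multiplicative assay error), then `(kout, IC50)` are estimated on the
pooled response by least squares on log-parameters, with each subject's
production rate constrained to its observed predose baseline
(`kin = kout · R0`, R0 = mean of that subject's negative-time samples,
the same convention as percent-of-predose normalization). IC50 refers
to **total** blood concentration; scaling to unbound potency is a
one-line composition with `binding_params()` left to the user, since
binding in the target species is often unmeasurable.

The model reports both the clearance rate `kout` and the derived
half-life `ln 2/kout` and never forces them to agree with an externally
quoted half-life: the two published dog-study values (k ≈ 0.26 h⁻¹ and
t½ ≈ 3.7 h) are mutually inconsistent by ln 2, and the package treats
the rate constant as primary.

## Effect metrics

`normalize_to_predose()` divides by the mean of the predose samples
(default −24 h and −1 h) and stores that mean so the transformation
inverts exactly. `auec_reduction()` is the time-averaged
linear-trapezoid area of percent reduction over a dosing interval. The
**t = 0 convention**: at once-daily steady state the effect at dose
time equals the trough effect, so a 0/4/24 h design uses the 24-h value
at 0 h — from reductions of 60/90/60 % this yields the 75 % interval
average. Group summaries use arithmetic means (the mean ± SEM
convention); significance testing is deliberately out of scope and left
to `aov`/`TukeyHSD` and friends.

## Plaque and glia quantification

The brightfield pipeline operates in optical-density space,
`OD = −log10(I)` with intensities clipped at 1/255 so saturated pixels
stay finite. The stain matrix is the standard hematoxylin/DAB basis
completed by the cross-product residual vector; `color_deconvolve()`
inverts it per pixel and clips negative amounts.

Parameters that the printed method leaves open were fixed once,
documented here, and exposed as arguments:

* **Nuclear vicinity**: 5 px disk dilation. "Within nuclear vicinity"
  and "sufficiently detached" are not quantified anywhere; 5 px is the
  scale of a nuclear radius at the export magnification used by the
  generators.
* **Adaptive threshold**: local mean over a 101-px boxcar plus an
  offset of 0.1 OD. The window must exceed the largest plaque diameter
  (~50 px) for the local mean to stay background-dominated.
* **Granule rejection**: objects < 25 px, the lower bound of the
  intracellular class; no shape criterion is applied because none is
  stated.
* **Class bounds are closed above**: exactly 200 px is intracellular,
  exactly 1000 px a small plaque. Classification applies the
  intracellular rule (size band *or* nuclear proximity) before the size
  rules, so a nucleus-adjacent object of any size is intracellular.
* **Connectivity** is 8-neighbour; ROI edges clip objects and the
  clipped area counts as-is.
* **Area fraction** counts all retained (classified) deposit pixels
  within the ROI; granule pixels are excluded with the objects.

Glia clusters are counted per channel with an Otsu threshold computed
from ROI pixels only — making the count invariant to positive intensity
rescaling — followed by the same labelling and a minimum cluster area
(20 px). Triple-stained material is treated as independent single
channels; no spectral unmixing is attempted. `correlate_pathology()`
reports Pearson r², the two-sided p value, the least-squares line and a
pointwise 95 % confidence band.

## Synthetic data: what it emulates, and what it does not

The generators' defaults are the study conditions the estimators are
meant to face, chosen once:

* `gen_pk_profile()`: one-compartment regimes per species — mouse
  CL 16 ml/min/kg, t½ 3.6 h, F 37 %; rat CL 52, t½ 2.7 h, F 92 %; dog
  CL 0.4, t½ 36.2 h, F 62 % — with serial-sampling time grids dense
  enough that trapezoid error stays under the 2 % closed-loop
  tolerance, and lognormal concentration noise.
* `gen_dose_response()`: vehicle + 0.3/1/3/10/30 µmol/kg, n = 5 per
  group, true ED50 1.6 µmol/kg, Hill 1, 10 % lognormal noise on
  analyte values (concentrations are non-negative; percents get
  Gaussian noise elsewhere).
* `gen_dog_study()`: n = 4 dogs, predose sampling at −24/−1 h and
  post-dose to 168 h, baselines lognormal around 6000 pg/ml (CV 0.2),
  blood forcing peaking at 0.7 µM with the dog terminal rate, true
  IC50 0.059 µM and kout 0.26 h⁻¹, 10 % residual noise. With these
  parameters suppression reaches ~20 % of baseline by 12–48 h; recovery
  at one week is substantial but incomplete because blood levels are
  then still near the IC50 — the model is allowed to say so rather than
  being bent to a printed recovery time.
* `gen_section_image()`: 640×640 px sections, hard-edged (non
  anti-aliased) disks drawn from the same stain basis the pipeline
  inverts, Poisson-disk-style placement with margins that keep free
  plaques outside every nuclear vicinity, and planted glia clusters
  coupled to deposits with probability `glia_coupling`.

Because placement forbids overlap and drawing is noiseless, the imaging
closed loop is **exact**: recovered pixel sets equal planted masks and
per-category counts equal the truth. That validates the pipeline's
logic — deconvolution, exclusion, thresholding, classification — not
its robustness to real histology: stain variability across scanners,
touching/overlapping deposits, anti-aliased or out-of-focus edges and
section artefacts are all outside what a passing test demonstrates.
Likewise the PK/PD loops validate estimator correctness under the
stated noise model, not under model misspecification (multiphasic
absorption, circadian baselines, assay drift).

Problem sizes used by the acceptance script — 200 simulated rat studies
for the ED50 median, 50 dog studies for the IC50/kout medians, single
sections per imaging condition — were chosen so the whole script
completes in about a minute while leaving the medians' Monte-Carlo
error well inside the tolerances being checked.

## Known limitations

* One-compartment forcing only; distributed brain compartments and
  population (mixed-effects) estimation are out of scope.
* The 4PL SE is asymptotic; for heavily saturated designs a profile or
  bootstrap interval would be more honest (the fit flags those designs
  instead).
* The segmentation has no shape features and no stain normalization;
  it is faithful to the printed method, not a general histology tool.
* `fit_turnover()` pools subjects with a shared (kout, IC50) and
  per-subject baselines; between-subject parameter variability is
  absorbed into residual error.
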