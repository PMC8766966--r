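---
title: "Salivary TDM: calibration, validation metrics and adherence concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary TDM: calibration, validation metrics and adherence concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivatdm)
```

## Why saliva, and what this package computes

Poor adherence to antihypertensive medication is a leading cause of apparent
treatment failure. Therapeutic drug monitoring (TDM) — measuring the drugs or
their metabolites in a biological fluid — is the most specific way to verify
intake, and multi-drug panels distinguish partial from complete
non-adherence. Plasma is the reference matrix but needs venipuncture and
trained staff; urine is easy but pharmacokinetically erratic. Saliva can be
collected anywhere in a minute with an absorbent-swab device, which makes it
attractive for unannounced adherence checks that defeat "white coat
adherence".

`salivatdm` implements the computational side of a quantitative LC-MS/MS
salivary assay for a 16-analyte antihypertensive panel (14 drugs, 2 active
metabolites): the calibration/QC design arithmetic, the weighted
through-origin quadratic calibration model and its inversion, the FDA/EMA
bioanalytical validation battery, signal-to-noise limit determination,
collection-device retention analysis, and multi-matrix adherence
classification with concordance statistics. Raw instrument data for the
assay are not public, so the package also ships a synthetic signal generator
that reproduces the statistical structure the pipeline assumes; every stage
is tested end to end against generator truth.

## The assay design

Each analyte's calibration runs from a top standard STD9 (the upper limit of
quantification, ULOQ) down to STD1 (the lower limit of quantification, LLOQ)
by eight serial 1:1 dilutions, so STD1 = STD9/256. Quality controls sit at
0.8, 0.1 and 0.01 of STD9 (H, M, L). Reported concentrations are rounded
half away from zero at 2 decimal places while all arithmetic keeps full
precision — the convention under which every printed STD1 of the panel
matches STD9/256 exactly.

The limit of detection (LOD) is stored as an empirical per-analyte value
rather than derived from the LLOQ: the dilution of the lowest standard stops
at a signal-to-noise ratio of 3, which lands on a different dyadic step for
each analyte (for sacubitril it is LLOQ/8, for valsartan LLOQ/16, and for
atenolol the recorded 1.91 ng/ml is not exactly LLOQ/2 = 1.95). Electrospray
polarity is carried as metadata only.

```{r design}
design <- default_assay_design()
design_table(design)
```

The per-analyte internal-standard assignment is not part of the published
design; the package assigns each isotope-labelled IS to its parent drug
(atenolol-d7, nifedipine-13C8, amlodipine-d4, telmisartan-13C-d3) and the
quinoxaline analog QX to the remaining analytes, the usual convention when
labelled standards exist for a subset of the panel.

## Calibration model

The response is modelled as a quadratic through the origin,

$$ y(c) = a\,c + b\,c^2, \qquad a > 0, $$

fitted by weighted least squares with $1/x$ weighting by default. Weighting
by the inverse concentration keeps relative accuracy at the bottom of a
256-fold range where absolute responses differ by more than two orders of
magnitude. The coefficients solve the closed-form 2×2 weighted normal
equations, so the fit is deterministic; `stats::lm` on the same design
matrix is used as an independent cross-check in the test suite, never as the
implementation.

Numerical and structural choices:

* **Curvature is unconstrained in sign** (detector saturation gives $b<0$,
  ionization enhancement can give $b>0$), but an accepted curve must be
  monotone increasing on $[0, \mathrm{ULOQ}]$, i.e. $a + 2b\,\mathrm{ULOQ} > 0$.
  This makes the in-range root of the inverse unique; a curve that turns
  over inside the range is rejected at fit time rather than silently
  inverted on the wrong branch.
* **Inversion** uses the numerically stable root
  $c = 2y/(a + \sqrt{a^2 + 4by})$, which degrades gracefully to $y/a$ as
  $b \to 0$; a quadratic term below $10^{-12}\,a$ is treated as zero.
* **$r^2$** is the weighted coefficient of determination about the weighted
  mean response (the standard WLS definition). The uncentered through-origin
  variant is deliberately not used: it inflates the statistic and would make
  the conventional 0.996 acceptance floor meaningless. A negative value is
  reported as-is with a warning — it flags a pathological fit.
* **Response variable**: analyte/IS peak-area ratio when an IS is assigned
  (`response_mode = "is_ratio"`, the default), raw analyte area otherwise.
  Peak-area integration with an IS in every sample admits both readings;
  the ratio is the field convention and is what makes the IS-normalized
  matrix effect meaningful. Recovery, extraction efficiency and matrix
  effect always use raw analyte areas, per their definitions.

Every result of `inverse_predict()` carries a qualifier: `below_lod`,
`below_lloq` (detected, quantification error risk above 20%), `quantified`,
or `above_uloq`, with half-open boundaries (exactly the LOD is detected,
exactly the LLOQ is quantified).

## Validation battery

Accuracy is `100 * mean(back-calculated)/nominal`; imprecision is the
relative standard deviation (sample sd over mean). Intra-day imprecision
uses the five replicates of one session; inter-day imprecision pools all
back-calculated values across the six sessions — the maximal
degrees-of-freedom reading of a multi-session design. The RSD of session
means is available behind `inter_method = "session_means"` because the
choice is genuinely open.

The three signal-ratio metrics follow the post-extraction addition scheme:

* recovery `REC = pre-spiked / neat` per session,
* extraction efficiency `EE = pre-spiked / post-spiked` per session,
* matrix effect `ME = post-spiked / neat − 1` per blank-matrix lot
  (suppression negative), and
* the IS-normalized matrix effect, the ratio of analyte/IS area ratios
  between post-spiked and neat injections per lot.

These satisfy the algebraic identity `REC = EE × (1 + ME/100)` on any common
triplet, which the tests verify exactly on generator data and, within 2%
relative, on 46 of the 48 rows of the bundled published reference metrics
(the two exceptions, sacubitril M and amlodipine M, are internally
inconsistent as printed and are asserted as known anomalies rather than
silently dropped). For the signed effects the dispersion is reported as
`100 * sd / (100 + mean)` — the RSD of the underlying response ratio — which
stays well defined when the mean effect crosses zero.

Compliance bounds are strict inequalities: bias and both RSDs below 15% at
QC levels, below 20% at the LLOQ. Failing cells are flagged, not rejected: a
panel assay remains fit for adherence screening with documented exceptions
at the very low end, and the flags preserve that distinction.

**Limits.** The LLOQ is the lowest dilution level satisfying |bias| < 20%,
RSD < 20% and S/N > 5 jointly; the LOD is the lowest level with S/N ≥ 3.
S/N is peak height divided by the standard deviation of blank peak heights
from the same source — the simplest estimator, kept pluggable via the
`noise` argument, since only the ratio thresholds are prescribed.
`LOD ≤ LLOQ` is enforced. **Selectivity** follows the customary guideline
thresholds (blank analyte response below 20% of the mean LLOQ response,
blank IS response below 5% of the IS response), strict at the boundary.

**Device retention.** Loss through the collection swab is
`100 * (post − pre)/pre` with three severity tiers: severe (≤ −50%),
moderate (−50%, −20%], negligible (|loss| < 20%, consistent with casual
error) and increase (≥ +20%). On the bundled reference table this
classifies amlodipine, telmisartan, doxazosin, nebivolol and
hydrochlorothiazide as severely retained in saliva — the drugs for which
salivary false negatives are a real risk.

## Adherence classification and concordance

A sample is adherence-positive from the LOD upward, not the LLOQ: sub-LLOQ
but supra-LOD saliva signals with clean peaks are reliable evidence of
intake even though their quantification error exceeds 20%. Concordance
against a reference matrix reports sensitivity, specificity and accuracy
from the matched 2×2 table; a margin with no reference negatives leaves
specificity not-applicable rather than inflating it to 100% on all-adherent
cohorts. Three-matrix agreement counts matches fully confirmed (3/3
matrices agreeing with the majority call) and partially confirmed (≥ 2/3).
Saliva/plasma ratios are summarized per drug as median and quartile-based
IQR (R's default inclusive quantile convention) with Pearson correlation by
default (`method = "spearman"` available), requiring at least three pairs.

The published patient-cohort results expose a genuine ambiguity: reported
saliva medians for some drugs (olmesartan 0.22 ng/ml) sit below the design
saliva LOD (0.49 ng/ml), so patient calls must have used a lower
instrument-level limit set. The package therefore takes the limit set as an
explicit input (`cohort_concordance(samples, limits)`) and deliberately does
not guess a reconciliation.

## What the generator emulates — and what it does not

`generator_config()` encodes the study conditions: 6 validation sessions, 5
intra-day replicates, 6 blank-saliva lots, intra- and inter-day CVs of 5%,
extraction efficiency 0.90, mean matrix effect −5% with a between-lot sd of
3 points. Noise is multiplicative lognormal throughout: proportional RSDs
across a 256-fold concentration range imply heteroscedastic, not additive,
error. Per-analyte slopes are scaled so the top standard reads ~10^6 area
counts; curvature defaults to −10% of linearity at the ULOQ (mild detector
saturation).

Three structural choices matter for interpreting test results:

* **The IS shares a per-injection instrumental factor (CV 3%) with the
  analyte, and the configured intra-/inter-day CVs apply to the
  quantification response itself.** An internal standard exists precisely to
  cancel injection-level variability, so the analyte/IS ratio must be *less*
  noisy than the raw area, not more. The IS is also co-suppressed with its
  analyte (`is_me_share = 1` by default), which centres the IS-normalized
  matrix effect on zero.
* **Blanks are unspiked donor saliva**: neither analyte nor IS, only a
  folded-normal baseline anchored so that S/N = 3 at each analyte's
  empirical LOD. This choice ties the noise floor to the design's recorded
  detection limits instead of introducing an arbitrary scale.
* **Device retention applies only to saliva patient samples and dedicated
  retention experiments**, never to calibration standards or QCs — standards
  meet the device only after collection in the described workflow.

The patient cohort draws 1–3 prescribed drugs per patient (54/30/16%
weights), lognormal plasma levels around drug-typical medians, saliva as
plasma × partition ratio × device retention × lognormal inter-patient noise
(sd 0.5), and urine as plasma × 25 with sd 0.8. Partition ratios and plasma
medians default to the bundled cohort reference values; drugs without a
reported plasma median use the geometric mid-range of their calibration
interval and a neutral partition ratio of 1. The reference retention table
prints a complete (−100%) saliva loss for doxazosin, yet the same assay
reports measurable salivary doxazosin in patients; the generator resolves
this inconsistency with a retention of 0.01, preserving the severe-loss
class without making the drug undetectable by construction.

The generator does **not** emulate pharmacokinetics (absorption,
elimination, time since dose), salivary pH dependence of partitioning,
protein-binding mechanisms, chromatographic interference, or peak
integration. Passing tests therefore demonstrate that the pipeline's
statistics recover known signal-model truth under realistic variance
structure — not that the assay's published numbers would be reproduced from
raw instrument data, which are not available.

## Problem sizes and tolerances

The test suite and acceptance script use: 500 seeds for the calibration
r² ≥ 0.996 check (the level is reported at the 5th percentile of seeds); one
full 16-analyte batch (6432 records) for the compliance bound; 40 seeds of a
single-analyte batch for the EE/ME recovery distribution; 200 patients for
the saliva/plasma median recovery, where the pooled truth-normalized median
is the estimator — per-drug medians at ~36 pairs per drug are too noisy for
a ±15% band at the generator's inter-patient sd of 0.5, so the per-drug
check would test sampling noise rather than the pipeline. Exact algebraic
identities are asserted at 10^-10 to 10^-12 relative; coefficient recovery
on noiseless data at 10^-9.

## Known limitations

* The pipeline consumes integrated peak areas and heights; nothing upstream
  of integration is modelled.
* Carry-over, stability and dilution-integrity tests are out of scope, as
  is any therapeutic-range interpretation — for antihypertensives the
  assay is a (semi-)quantitative adherence instrument, not a dosing tool.
* The published per-patient calls behind the reported cohort
  sensitivity/specificity are unavailable, so concordance is validated on
  synthetic cohorts only, where the generator defines truth.
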