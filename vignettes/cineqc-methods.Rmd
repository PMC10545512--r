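---
title: "Quality-controlled analysis of short-axis cine CMR segmentations: methods and design"
author: "cineQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-controlled analysis of short-axis cine CMR segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineQC)
```

## What the package does

cineQC implements the quality-controlled end of an automated cardiac-MR
analysis pipeline for short-axis (SAX) cine segmentation stacks. Large
clinical imaging archives are messy: segmentation protocols differ between
departments (myocardium often unannotated at end-systole, papillary muscle
sometimes in and sometimes out of the blood pool), ground-truth contours
contain errors, and automated segmentation models occasionally produce
anatomically impossible output. The package provides, on a common data
model:

* a **rule engine** for screening segmentations — used both as quality
  assurance of ground truth (QA, flag/exclude only) and as post-analysis
  quality control of model output (QC, with automatic correction of simple
  errors);
* **biventricular volumetry** (EDV, ESV, SV, EF, LV mass);
* **papillary-muscle exclusion** from blood pools by Otsu thresholding of
  the within-mask intensity histogram;
* a **marginalized partial-label loss** for training segmentation networks
  on cohorts with inconsistent annotation protocols;
* **agreement statistics** (Dice, Bland–Altman, median absolute errors,
  Mann–Whitney/Wilcoxon tests with Bonferroni tiers, stratified reports);
* a **synthetic phantom generator** with analytically known biomarkers and
  an injector for every defect class the rules are designed to catch.

Because real clinical datasets of this kind cannot be redistributed, every
empirical claim in the package is demonstrated on the phantom generator;
the generator is therefore first-class, tested code, not a fixture.

## Data model and conventions

A `LabelStack` is one phase's 3D integer label volume, indexed
(slice, row, col) with slice 1 the most basal slice, plus in-plane voxel
spacing and the centre-to-centre slice spacing (both mm). The canonical
label vocabulary is background = 0, LV blood pool (LVBP) = 1, LV
myocardium (MYO) = 2, RV blood pool (RVBP) = 3; papillary-refined stacks
may add PAP = 4. Files that use a permuted encoding are remapped to this
vocabulary on load; an *unknown* voxel value is always an error, never a
silent coercion. On disk the canonical form is NIfTI-1 plus a JSON sidecar
(label map, phase tag, spacings, slice direction); sidecar spacings
override NIfTI header values because headers in exported archives are
frequently wrong. DICOM ingestion is deliberately out of scope: header
harmonization is site-specific engineering, and the NIfTI+JSON form is the
interchange point.

The voxel volume is `row spacing x col spacing x slice spacing`, i.e. the
slice spacing absorbs slice thickness plus any inter-slice gap. Volumes
are plain voxel-count sums (Simpson-style summation over slices) with no
partial-volume weighting — this matches mask-based ground truth and keeps
the analytic oracle exact. Connectivity is 8-neighbour within a slice;
face adjacency across slices is used only by the 3D heart-component
check. SAX voxels are strongly anisotropic (slices of 6–10 mm against
in-plane spacings near 1–2 mm), and contours are drawn per slice, so
per-slice 2D reasoning matches how the data are produced.

## The screening rules

`runQaGt()` (cohorts of ground truth) and `runQcPost()` (single model
outputs) share one battery of deterministic checks:

| rule id | what it detects |
|---|---|
| `frame_completeness` | a required phase missing or all-background (no SV/EF possible) → exclusion |
| `coverage_extent` | segmented LV length below `minLvExtentMm` (default 40 mm) |
| `coverage_apex` | LVBP area at the most-apical segmented slice above `apicalAreaFractionMax` (default 0.5) of the maximal slice area — a truncated apex |
| `gap` | a slice with no voxels of a label strictly between two slices that have it |
| `myo_breach` | an in-plane 8-connected path of non-MYO voxels from the LV blood pool to the image border (hole in the wall, or ring absent) |
| `lv_rv_contact` | LV and RV blood pools 8-adjacent (no septal myocardium) |
| `external_component` | 3D foreground components disconnected from the heart (the largest component) |
| `volume_range` | a biomarker outside its plausibility interval |
| `sv_discordance` | relative LV/RV stroke-volume difference above 25% |
| `duplicate` | identical non-empty voxel content across studies/phases |

Design choices that were genuinely open:

* **SV discordance denominator.** The clinical rule is stated as an SV
  difference above 25% without a denominator; we use the mean of the two
  stroke volumes, which is symmetric in LV and RV.
* **Plausibility ranges** (LVEDV/RVEDV 20–800 mL, LVESV/RVESV 10–700 mL,
  LVM 20–500 g), the 40 mm minimal LV extent, the 0.5 apical area
  fraction and the 2-voxel noise-component size are package defaults
  chosen to be deliberately permissive — they should catch unit-level and
  gross segmentation errors, not borderline physiology. All are
  configurable through `screeningConfig()`.
* **Breach check scope.** The myocardial-ring breach check runs on every
  slice containing LVBP, whether or not that slice has any myocardium: an
  entirely absent ring is the extreme case of a breached ring. This makes
  the check sensitive to protocol defects where the myocardium is simply
  missing, at the cost of flagging protocols that *intentionally* omit ES
  myocardium — such cohorts should run with the affected phase excluded
  from anatomy checking or accept review flags.
* **QA never edits ground truth**; only QC applies corrections, and only
  the one correction that is unambiguous: deletion of foreground
  components disconnected from the heart. Gaps, breaches, implausible
  volumes and SV discordance are reported for review but never modified.
  When corrections are applied, external components are removed *first*
  and the remaining checks run on the corrected segmentation, so a
  cleaned study is not also flagged for the blob it no longer contains.
* **Tie-break** for equal-sized largest components: the component whose
  smallest (slice, row, col) index is lexicographically least is kept.
  This makes correction deterministic; it has no clinical meaning.
* Empty stacks are completeness failures, not duplicate candidates.

Idempotence holds by construction: a second `runQcPost()` pass on a
corrected study finds a single foreground component and produces an empty
plan.

## Volumetry

For each ventricle, ED and ES phases come from study metadata when
declared (clinical datasets do not always segment LV and RV in the same
frame); otherwise ED is the phase of maximal and ES of minimal non-zero
blood-pool volume. EF = 100·(EDV − ESV)/EDV, reported as missing when
EDV = 0. LV mass is the myocardial volume at the LV ED phase times a
tissue density of 1.05 g/mL — the field-standard constant, configurable —
and is computed at ED only because ES myocardium is frequently
unannotated. Papillary handling is a provenance flag on the result: with
`papillaryMode = "exclude"` the blood pools of the phases in use are
refined (below) before volumes are taken, and by default the removed
voxels go to a dedicated PAP class so LV mass is *not* silently inflated.

## Papillary exclusion by Otsu thresholding

On bright-blood (bSSFP) cine, blood is bright and muscle dark, so
papillary muscle inside a blood-pool mask separates from blood by
intensity. Per ventricle and per phase (histograms are not pooled across
regions, since coil shading varies), the within-mask histogram (256
equal-width bins) is split at the threshold maximizing the between-class
variance w0·w1·(mu0 − mu1)^2, ties resolved toward the lowest threshold;
voxels below the threshold are reassigned, except dark islands of at most
2 voxels, which are treated as noise and left as blood. A degenerate
histogram (all mass in one bin) makes the refinement a no-op with a
warning note.

Known limitation, stated plainly: Otsu's criterion assumes two
populations of non-negligible weight. If a blood pool contains *no* dark
tissue, the criterion will happily split the bright mode in half. In real
bSSFP ventricles trabeculation and papillary muscle are always present at
a volume fraction well above the criterion's breakdown point (around 0.2%
of the mask under the phantom's contrast of 20 noise SDs), so the
generator's defaults include papillary inclusions in both ventricles; but
the refinement should not be applied to sequences or masks where no dark
class can exist. The polarity is configurable for dark-blood sequences.

## The marginalized partial-label loss

Training on mixed-protocol cohorts requires a loss that is well defined
when a class is unannotated in a frame. Rather than masking voxels, each
absent class's predicted probability is folded into background —
`q_bg = p_bg + sum of p_c over absent c` — and the composite
cross-entropy + soft-Dice loss (Dice per class
`(2*sum(p*g) + eps)/(sum(p) + sum(g) + eps)`, eps = 1e-5, averaged over
present non-background classes) is computed on the folded distribution.
Folding was chosen over voxel-masking because it preserves per-voxel
normalization and yields two exact, testable contracts: (i) with all
classes present the loss *equals* the standard composite loss, and (ii)
with a class absent the loss is *invariant* to any per-voxel transfer of
predicted mass between that class and background. These contracts define
the implementation's behaviour; they are verified against an
independently-coded standard loss in the test suite.

## Agreement statistics

Dice is reported in percent; a label empty in both stacks is *missing*,
not 100%, so absent classes (MYO at ES) cannot inflate medians. Dice
values are pooled across phases before taking per-label medians;
per-phase reporting is available by calling `diceScore()` per phase.
Bland–Altman limits are bias ± 1.96 SD of the differences; Pearson r is
undefined on constant input. Absolute-error summaries use the median and
the p75 − p25 interquartile range with linear interpolation (quantile
type 7). Group comparisons use the Mann–Whitney U test between groups and
the Wilcoxon signed-rank test against zero within groups, with
Bonferroni-adjusted significance tiers alpha/nTests for alpha in
{0.01, 0.001, 0.0001}. Stratified reports compare each stratum against a
reference stratum and mark strata below the minimum size as insufficient
rather than dropping them.

## The phantom generator

The generator emulates the geometry and contrast that the rules and
volumetry actually consume; it does not simulate MR physics, motion, or
trabecular detail. Per phase the LV endocardium is a half-ellipsoid of
revolution — radius profile `r(z) = R*sqrt(1 - (z/L)^2)` from full radius
at the base to zero at the apex — the myocardium a closed annulus of
constant thickness, and the RV a crescent sharing the septal border with
the myocardium over an angular window. A voxel is foreground iff its
centre lies inside the continuous solid, making the voxel-count volume an
unbiased midpoint-rule estimator whose error vanishes as spacing shrinks
(the suite checks monotone convergence over 2, 1, 0.5 mm). Ground-truth
biomarkers are computed from the *continuous* geometry by adaptive
quadrature, independent of any grid.

`randomPhantomSpec()` draws a physiologically plausible subject: LVEDV
uniform on 100–220 mL, LVEF on 45–58%, LV long axis 72–88 mm shortening
4–10 mm at ES, wall 7–10 mm thickening 2–4 mm, RVEDV within 0.85–1.05 of
LVEDV and RVSV within 0.92–1.08 of LVSV (so clean phantoms always satisfy
the 25% SV-concordance rule with margin), RV angular extent 2.4–3.0 rad.
Intensities are bSSFP-like — blood 300, myocardium 100, background 50,
Gaussian noise SD 10 — and papillary inclusions (two LV, one RV per
phase, at myocardial intensity but blood-pool *label*, per the inclusive
"protocol A") are placed inside the cavities by construction. The EF
range is kept below typical hyperdynamic values so that the
SV-discordance defect (doubling the ES RV) provably crosses the 25%
threshold for every seed; this is a property of the study conditions, set
once, not a tuning knob.

Each defect kind in `defectSpec()` names the rule it is designed to
trigger, and its default parameters guarantee the trigger for any
generator draw: e.g. 7 dropped basal slices leave under 40 mm of LV; 4
dropped apical LV slices leave an apical area ratio above 0.5; spacing
scales 2.2 / 0.4 push volumes past 800 / under 20 mL; the ES RV mirror
duplication at least roughly doubles RV ESV. The enlargement variant of
`sv_discordance` is implemented as an exact mirror about the column axis
(a voxel bijection) rather than interpolation, so the doubling is exact
and the defect introduces no resampling artefacts.

What passing these tests shows — and what it does not: the rules fire
with 100% sensitivity and zero false positives *on phantoms whose defects
are unambiguous by construction*. Real contours have partial-volume
boundaries, basal-plane ambiguity and inter-observer variability that the
phantom does not model; on real data the same rules will sit on a softer
operating point, which is why flagged studies go to clinician review
rather than automatic exclusion.

## Numerical choices and problem sizes

Quadrature for analytic truth uses `stats::integrate` at relative
tolerance 1e-10. Otsu tie-breaks take the lowest threshold; the argmax
tolerance is relative (1e-12) to the best criterion value. Cross-entropy
clamps probabilities at 1e-12. All screening runs are exactly
deterministic: identical inputs give byte-identical reports, entries
sorted by (rule, phase, location).

The documented study conditions use two resolutions: 84x84x12 voxels at
2x2x8 mm for the screening battery (a realistic clinical SAX footprint;
600 phantom studies screen in about a minute) and 160x160x48 at
1x1x2 mm for volumetry and papillary accounting, where discretization
error must be well under the 3% / 2-percentage-point claims (observed
errors are an order of magnitude smaller). Sensitivity runs use 50 seeded
phantoms per defect kind and 50 clean phantoms for specificity.

## Known limitations

* The external-component correction assumes the heart is one connected
  foreground object; protocols that legitimately omit ES myocardium
  disconnect the RV from the LV in 3D and should disable corrections (or
  review flags) for such phases.
* Papillary refinement requires a genuinely bimodal within-mask
  histogram; see above.
* The pipeline's segmentation step is a pluggable contract
  (`passthrough` for stored labels, `command` for an external
  executable); no network or training loop is included, and the loss is
  provided as a pure function for external training code.
* Long-axis views, full-cycle (all-frame) analysis, strain and regional
  metrics, and body-surface-area indexing are out of scope.
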