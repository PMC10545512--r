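# cineQC

Quality-controlled quantification of biventricular function from
short-axis (SAX) cine cardiac-MR segmentation stacks.

Large clinical CMR archives are unstructured: annotation protocols vary
(myocardium often unannotated at end-systole; papillary muscle included in
or excluded from the blood pools), ground-truth contours contain errors,
and automated segmentation models occasionally produce anatomically
impossible output. cineQC is for researchers processing such archives —
or validating segmentation models against them — who need the
*quality-controlled* part of the analysis to be automatic, deterministic
and auditable.

## What it computes

For label stacks with classes background / LV blood pool (LVBP) / LV
myocardium (MYO) / RV blood pool (RVBP):

* **Biomarkers** — per ventricle EDV, ESV, SV = EDV − ESV,
  EF = 100·(EDV − ESV)/EDV, and LV mass = V_MYO(ED) × 1.05 g/mL, all from
  voxel-count Simpson summation (voxel volume = row × col × slice
  spacing).
* **Screening rules** — frame completeness, base-to-apex coverage,
  inter-slice gaps, myocardial-ring breaches and LV/RV contact,
  disconnected foreground components (with automatic deletion in QC
  mode), biomarker plausibility ranges, LV/RV stroke-volume discordance
  (|LVSV − RVSV| / mean > 25%), and cohort-wide duplicate detection.
  Ground-truth QA only flags/excludes; post-analysis QC may auto-correct
  the single unambiguous error class (components outside the heart).
* **Papillary exclusion** — Otsu threshold of the within-mask intensity
  histogram (between-class variance w0·w1·(μ0 − μ1)², lowest-threshold
  ties), removing dark voxels from the blood pools per clinician
  preference.
* **Partial-label loss** — cross-entropy + soft Dice with absent classes
  folded into background, for training on mixed-protocol cohorts.
* **Agreement statistics** — Dice (% with both-empty = missing),
  Bland–Altman bias and ±1.96 SD limits, median absolute error (IQR),
  Mann–Whitney U / Wilcoxon signed-rank with Bonferroni tiers, and
  stratified reports by disease group, vendor or field strength.
* **Synthetic phantoms** — SAX studies with analytically known
  biomarkers (half-ellipsoid LV, annular myocardium, crescent RV,
  papillary inclusions, bSSFP-like intensities) plus an injector for
  eleven annotation-defect classes, each designed to trigger a named
  screening rule.

## Worked example

```r
library(cineQC)

ph <- generatePhantom(randomPhantomSpec(7), studyId = "demo")
ph$truth                       # analytic ground truth (continuous geometry)
#> BiomarkerSet (papillary included)
#>   LV: EDV 218.7 mL, ESV 109.0 mL, SV 109.7 mL, EF 50.2%, mass 125.8 g
#>   RV: EDV 228.4 mL, ESV 124.5 mL, SV 103.8 mL, EF 45.5%

computeBiomarkers(ph$study)    # voxel-count volumetry on the 1.8x1.8x8 mm stack
#> BiomarkerSet (papillary included)
#>   LV: EDV 219.0 mL, ESV 109.0 mL, SV 110.0 mL, EF 50.2%, mass 124.8 g
#>   RV: EDV 225.7 mL, ESV 127.6 mL, SV 98.0 mL, EF 43.4%

# corrupt the study with a blob of "blood pool" far outside the heart,
# then let post-analysis QC repair it
bad <- injectDefect(ph$study, defectSpec("stray_component", size = 50L))
qc  <- runQcPost(bad)
qc$report
#> FlagReport: 1 entry
#>              rule_id  severity phase  location
#> 1 external_component corrected    ED 50 voxels
#>   deleted disconnected component of 50 voxels outside the heart (external-component deletion)

identical(voxels(stacks(qc$study)$ED), voxels(stacks(ph$study)$ED))
#> [1] TRUE                     # restored voxel-exactly
```

The recovered LV volumes sit within a fraction of a percent of the
analytic truth even at clinical 1.8 × 1.8 × 8 mm resolution (the RV,
being a thin crescent, carries slightly more discretization error); the
QC report says exactly what was changed and why, and a second pass makes
no further corrections.

A command-line front end is installed with the package
(`system.file("cli", "cineqc", package = "cineQC")`) with subcommands
`phantom`, `qa`, `qc`, `biomarkers`, `papillary` and `run`, e.g.

```sh
cineqc phantom --seed 3 --out study_dir
cineqc run --manifest cohort.csv --out results/ --backend passthrough
```

## Documentation

The methods vignette (`vignettes/cineqc-methods.Rmd`) describes the data
model, each screening rule and its default thresholds, the volumetry and
papillary-exclusion algorithms, the loss contracts, what the phantom
generator does and does not emulate, and known limitations.
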