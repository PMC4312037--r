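# cardiomict

Quantification of murine myocardial infarction from delayed-contrast-
enhanced, prospectively gated cardiac micro-CT — with a fully synthetic
test bench.

## What this is for

Preclinical cardiology groups image mouse ischemia–reperfusion models
with gated micro-CT: a small-molecule iodinated agent (Iohexol) is
retained in necrotic myocardium, so the infarct stays bright 10–30
minutes after injection; a blood-pool agent then supports
left-ventricular volume and ejection-fraction measurement; TTC-stained
histology validates the infarct size. `cardiomict` implements that
analysis chain end to end:

- **phantom** — a digital heart (confocal ellipsoids, anterior apical
  infarct wedge, mono-exponential contrast washout, configurable noise,
  motion-streak corruption) with exact ground truth for EF, infarct
  fraction and tissue HU;
- **gating** — simulated ECG/respiration and the prospective dual-gating
  projection scheduler of a 1 Hz step-and-shoot scanner;
- **ct_quant** — HU calibration, threshold-constrained seeded region
  growing of the LV blood pool, myocardial banding, robust
  delayed-enhancement infarct thresholding, volumes and EF;
- **histo_quant** — color segmentation of TTC slice photographs and
  front/back slab integration of infarct percent;
- **stats** — cross-modality Pearson R² with explicit outlier exclusion,
  paired and Welch t-tests, agreement reports.

The central quantities are

EF = (V_dia − V_sys) / V_dia,  infarct% = 100 · |I| / |M ∪ I|,
HU(t) = A₀ e^(−λt),  HU = 1000 (μ − μ_w)/(μ_w − μ_a),

with the washout model calibrated exactly through the two measured time
points per tissue (blood 411→245 HU, infarct 431→281 HU, myocardium
182→139 HU at 13 and 30 min).

## Worked example

```r
library(cardiomict)

# one ischemia-reperfusion subject: true EF 0.36, true infarct ~32% of wall
sp <- phantom_spec(true_ef = 0.36, noise_sd_hu = 30, spacing_mm = 0.11, seed = 42)
sp$infarct_wedge <- infarct_wedge_for_fraction(sp$lv_cavity_semiaxes_dia_mm,
                                               sp$wall_thickness_mm, 0.32)

dia     <- build_heart_phantom(sp, "diastole", 13, agent = "blood_pool")
sys     <- build_heart_phantom(sp, "systole",  13, agent = "blood_pool", seed = 43)
delayed <- build_heart_phantom(sp, "diastole", 13, agent = "iohexol",    seed = 44)

q <- quantify_ct(dia$volume, sys$volume, delayed$volume)
#> V_dia 36.3 mm3 | V_sys 23.2 mm3 | EF 0.361 | CT infarct 31.8%
#> (ground truth: EF 0.36, infarct 31.7%)

slices <- render_ttc_slices(sp, thickness_mm = 1, pixel_size_mm = 0.05, seed = 45)
percent_infarct_histology(slices)
#> 34.2   (8 slices at 1 mm; both faces of each slab)

# published per-subject table: correlation with and without the
# motion-corrupted subject
print(agreement_report(table1_records(), exclude_ids = 5))
#> Cross-modality infarct agreement
#>   n = 8 subjects
#>   CT:        32.2 +/- 11.4 %
#>   histology: 30.5 +/- 7.8 %
#>   R^2 (all) = 0.6897 | R^2 (excl. 5) = 0.8329
#>   paired t-test p = 0.478
```

The segmented EF (0.361) and CT infarct percent (31.8%) recover the
phantom's ground truth; the histology estimate carries the expected
out-of-plane slab error of 1 mm slicing. The agreement report reproduces
both published correlations to four decimals from the packaged
per-subject table.

`run_all()` (or `Rscript inst/scripts/run_all.R --seed 17 --out results/`)
drives the whole study in one call: it simulates a cohort (default 8 IR +
7 control, one IR subject motion-corrupted), images and gates every
subject, runs both quantification arms, and writes the per-subject CSV
and the agreement report.

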