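# deltarad

Delta-radiomics of daily cone-beam CT (CBCT) for predicting genitourinary
(GU) toxicity during prostate radiotherapy.

## What this package is for

Prostate cancer patients treated with definitive radiotherapy receive a
CBCT scan at every treatment fraction for image guidance. Radiation-induced
inflammation plausibly changes prostate tissue texture days to weeks before
GU symptoms (CTCAE-graded frequency, nocturia, dysuria, urgency,
obstruction, incontinence) or urinary quality-of-life decline (IPSS) are
recorded. `deltarad` is a tested, reusable implementation of the full
longitudinal ("delta") radiomics analysis that investigates this signal:

1. **simulate** — a seeded phantom-cohort generator (clinical daily-CBCT
   datasets of this kind are not public) producing fractionated image
   series with a prostate-like ROI, gold-fiducial streak artifacts,
   per-fraction texture drift coupled (or not) to binary outcomes, and
   mixed fractionation schedules (80 Gy/40 fx, 70.2 Gy/26 fx);
2. **preprocess** — isotropic 1 mm resampling; fiducial artifact removal
   (`[μ_AL − 3σ_AL, μ_AL + 3σ_AL]` threshold in a 5 mm circle, plus streak
   spoke line masks); optional Collewet 3σ re-segmentation; uniform or
   Lloyd-Max quantization to G = 256 gray levels;
3. **extract** — 42 base radiomic features (3 first-order, 8 GLCM,
   13 GLRLM, 13 GLSZM, 5 NGTDM; 13-direction merged 3D matrices,
   26-connected zones/neighborhoods) + 6 volume-normalized variants +
   prostate volume;
4. **delta & bin** — per-fraction change `DRF = (RF_N − RF_1)/|RF_1|`,
   averaged in 20 Gy bins of accumulated biologically effective dose,
   `BED = n·d·(1 + d/(α/β))` with α/β = 3 Gy, aligning mixed schedules
   (one bin ≈ one treatment week: 6 fx at 2 Gy, 4 fx at 2.7 Gy);
5. **label** — acute GU (max CTCAE grade ≥ 2 after the bin's BED),
   sub-acute GU (post-treatment events, bin-invariant), and
   ΔIPSS = IPSS_f − IPSS_i (category 1 = improvement, ΔIPSS < 0);
6. **model** — 500-tree random-forest Gini ranking on all bins pooled,
   |r| > 0.8 correlation filtering, ≤ 7 features, per-bin logistic
   regression validated by 1000-iteration bootstrap leave-one-out AUC
   (median and 2.5–97.5 percentile CI).

See `vignettes/methods.Rmd` for the model assumptions, parameter
rationale, what the phantom does and does not emulate, and numerical
choices.

## Worked example

```r
library(deltarad)

cfg <- list(
  cohort = list(n_patients = 60, texture_effect_size = 3, seed = 101),
  model  = list(endpoints = "acute_gu", n_iter = 200, seed = 102)
)
m <- run_pipeline(cfg, out_dir = "run1")
print(m$models$acute_gu)
```

which prints (numbers produced by this exact code):

```
<drf_models> features: Global_Variance, NGTDM_Complexity, NGTDM_Strength_VN, Global_Skewness, GLSZM_LGZE, GLRLM_LRLGE, Prostate_Volume
  BED20   n=60  median AUC 0.756 (0.640-0.880)
  BED40   n=60  median AUC 0.623 (0.391-0.803)
  BED60   n=60  median AUC 0.600 (0.313-0.846)
  BED80   n=60  median AUC 0.427 (0.031-0.748)
  BED100  n=60  median AUC 0.324 (0.000-0.709)
  BED120  unevaluable (n=60 or single class)
```

Reading this: the forest selected at most seven delta-features (the
variance of the in-ROI intensities is the strongest drift carrier in the
phantom world); each `BEDxx` line is one logistic model on the DRFs
averaged up to that accumulated BED, with the median and 95% percentile
interval of its bootstrap leave-one-out AUC distribution. An AUC of
0.7–0.8 is conventionally "moderate", above 0.8 "strong"; the first line
says the signal is already detectable in the first ≈ week of treatment
(20 Gy BED). Performance decays at later bins in this phantom world
because the acute label at bin b counts only events with onset *after* b:
as b grows, fast-drifting patients whose events already occurred flip to
category 0, diluting the class signal. The 120 Gy bin is unevaluable here
because almost no acute event has onset past 120 Gy BED, leaving a single
class. `run1/` contains
`features.csv`, `drf.csv`, `labels.csv`, `cohort.json`, `models.json` and
`bootstrap_auc.csv` (box-plot-ready long format); rerunning the same
config reproduces them byte-identically.

A command-line driver with the same stages ships in
`inst/scripts/deltarad` (YAML config; see
`inst/extdata/example_cohort.yaml`).

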