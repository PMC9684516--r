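---
title: "Delta-radiomics of daily CBCT: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics of daily CBCT: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During definitive radiotherapy of prostate cancer, a cone-beam CT (CBCT) is
acquired at every treatment fraction for image guidance. Radiation-induced
inflammation of the prostate and urethra plausibly changes tissue texture
well before genitourinary (GU) symptoms are reported, so quantitative
texture features extracted from the daily CBCT — and more specifically
their *change over the course of treatment* — are candidate early
biomarkers of acute and sub-acute GU toxicity and of urinary quality of
life (IPSS).

`deltarad` implements that analysis end to end: per-fraction texture
feature extraction from the prostate ROI, normalization of each feature to
its first-fraction value, alignment of heterogeneous fractionation
schedules on a biologically-effective-dose axis, endpoint labeling, and
per-time-bin logistic models with random-forest feature selection and
bootstrap leave-one-out validation. Because clinical daily-CBCT datasets of
this kind are not public, the package ships a seeded phantom-cohort
generator so every stage is testable and the whole pipeline can be
exercised at realistic scale without any data download.

## Pipeline model, stage by stage

### Geometry and resampling

Volumes carry physical voxel spacing (default 0.9 × 0.9 × 2.0 mm, the
in-plane pixel size and slice thickness of clinical CBCT) with the origin
at the volume corner. Before feature extraction every volume/mask pair is
resampled to isotropic 1 mm voxels — trilinear for intensities, nearest
neighbor for the mask (a mask must never be smoothed, or partial-volume
blur grows the ROI). The output grid shares the input origin and rounds
the physical extent to the nearest voxel; resampling a constant field is
exact, and trilinear interpolation cannot overshoot the input range.
Resampling happens *first* so that the 5 mm artifact-removal radius below
is exact in millimeters.

### Fiducial streak-artifact removal

Implanted gold fiducials produce bright rods plus radial streak spokes on
the axial slices that contain them. The cleaning rule estimates an
acceptance range [μ_AL − 3σ_AL, μ_AL + 3σ_AL] from ROI voxels on
artifact-free layers, then on each artifact layer removes ROI voxels that
lie within a 5 mm circle of a fiducial *and* fall outside the range, plus
the voxels on straight line masks drawn from each such above-threshold
pixel back to the fiducial center (capturing spokes). Voxels on layers
without fiducials are never touched, and an error is raised if every layer
contains a fiducial (the threshold would be undefined). "Layers" are axial
slices, matching CBCT acquisition geometry; lines are rasterized with the
classic integer (Bresenham) walk since no rasterization rule is canonical.
Which pixels count as "distal" seeds is genuinely open; we seed a line
from *every* above-threshold pixel in the circle, which is conservative
(supersets of spokes are removed, never non-artifact layers).

### Re-segmentation and quantization

Collewet 3σ re-segmentation (IBSI rule RS:3σ) optionally restricts the ROI
to [μ_R − 3σ_R, μ_R + 3σ_R] before discretization; σ uses the population
(n) denominator throughout, and a constant ROI is returned unchanged. The
operation is deliberately not idempotent — a second pass sees new
statistics — and our tests document that.

Gray levels are discretized to G = 256 bins (8-bit, the conventional
choice for CBCT radiomics) by either of two quantizers:

* **uniform** — fixed bin number from the ROI minimum to maximum,
  half-open bins with the top bin closed, so min → 1 and max → G; and
* **Lloyd-Max** — minimum-mean-squared-error scalar quantization by Lloyd
  iteration on the empirical ROI distribution (boundaries = midpoints of
  representatives, representatives = conditional means), initialized from
  the uniform partition, deterministic, stopping when the MSE improves by
  less than 1e-7 or after 500 iterations.

Because the uniform quantizer's reported MSE uses the conditional mean of
each occupied bin as its reconstruction level — the only definition under
which a two-mode ROI split exactly at its gap has zero error — and Lloyd
iteration starts from exactly that partition, the Lloyd-Max MSE can never
exceed the uniform MSE; this is asserted property-style over hundreds of
random ROIs. If the ROI has no more distinct values than levels, each
value gets its own level and the error is exactly zero. The two pipeline
arms mirror the field's standard comparison: Lloyd-Max + Collewet
("Llo-1") versus uniform without re-segmentation ("Uni-0").

### Texture features

Exactly 42 base features are computed: 3 first-order (variance, skewness,
excess kurtosis — on the *continuous* re-segmented intensities, since
first-order statistics are conventionally pre-discretization), 8 GLCM, 13
GLRLM, 13 GLSZM and 5 NGTDM. GLCM and GLRLM accumulate the 13 unique 3D
directions at distance 1 and are merged across directions *before*
normalization (the "merged" aggregation of the standard MATLAB radiomics
toolbox); GLSZM zones and NGTDM neighborhoods are 26-connected and
mask-aware (out-of-mask neighbors are excluded from neighborhood
averages). NGTDM coarseness and strength follow Amadasun & King; the rest
follow IBSI formulas. Six volume-normalized (VN) variants — NGTDM
strength, busyness and coarseness, GLSZM GLN, GLRLM GLN and RLN — plus the
physical ROI volume complete the 49-name vector, so ⌈√49⌉ = 7 is also the
forest's features-per-split below.

The exact VN exponents are not uniquely fixed by the normalization
literature; we divide size-sensitive statistics (GLN, RLN, strength,
busyness) by the voxel count and multiply coarseness (which shrinks with
region size) by it. The convention is isolated in one function
(`volume_normalize()`) and covered by a duplication-invariance test: a
disjointly duplicated ROI doubles GLN and the voxel count, leaving GLN-VN
invariant.

Degenerate inputs are handled explicitly: a constant ROI has GLCM energy
1, contrast 0 and NGTDM s-vector 0; GLCM correlation is defined as 0 when
the gray-level variance vanishes; a single-voxel ROI has no voxel pairs
and raises an error naming the failing family.

### Delta features and BED binning

Each feature is normalized to its first-fraction value,
DRF = (RF_N − RF_1)/|RF_1| — the absolute value keeps the sign of the
change when the baseline is negative. Baselines with |RF_1| < 1e-12 would
produce unbounded ratios; those feature-patient pairs are flagged and
dropped (NA) rather than allowed to dominate the design matrix.

Accumulated biologically effective dose after k fractions of d Gy is
k·d·(1 + d/(α/β)) with α/β = 3 Gy for prostate. DRFs are averaged inside
half-open 20 Gy bins (b − 20, b] for b = 20…120 Gy; a bin is roughly one
week of treatment (6 fractions at 2 Gy/fx, 4 at 2.7 Gy/fx), which is what
lets 80 Gy/40 fx and 70.2 Gy/26 fx cohorts share one time axis. Fraction 1
(whose DRF is identically 0) is included in the first bin's average by
default (`include_first`, config-flippable); fractions beyond 120 Gy
accumulated BED are dropped, since the analysis window ends there.

### Endpoints

GU toxicities are CTCAE v5 events with grade, onset (as accumulated BED)
and phase. The acute label for bin b is 1 iff any during-treatment event
with onset *strictly after* b has grade ≥ 2 (the boundary is not specified
anywhere authoritative; strict inequality makes the label monotone
non-increasing in b, which is also property-tested). The sub-acute label
uses post-treatment events only and is bin-invariant by construction.
ΔIPSS = IPSS_final − IPSS_initial, and category 1 encodes ΔIPSS < 0 —
i.e. *improvement*; the convention is unusual but implemented literally,
and the baseline IPSS is always offered to the ΔIPSS models as a clinical
covariate. Onset is recorded in BED rather than calendar time so that
labels are schedule-invariant.

### Feature selection and validation

All BED bins are pooled into one cohort for feature selection (each pooled
row keeps its own bin's label for the acute endpoint), keeping the
selected features consistent across bins. Before pooling, every feature is
z-scored *within its bin*: delta features grow in magnitude with
accumulated dose, and that bin-level variance would otherwise dominate the
pooled rows and hide the within-bin class signal from the ranking (we
measured a feature with within-bin AUC 0.91 fall to pooled AUC 0.54 on raw
DRFs, and out of the top-7 selection entirely). Standardization is a
selection-phase device only — the per-bin logistic models below always
see raw DRFs — and leaves the correlation filter meaningful, since
Pearson correlations of within-bin z-scores reflect within-bin feature
redundancy rather than shared dose-response growth. A 500-tree random forest —
bags of ⌊2n/3⌋ patients drawn without replacement, 7 candidate features
per split, grown to purity — ranks features by Gini importance in the
"risk change per branch node" form: per tree, impurity-risk decreases are
accumulated per split feature and divided by the tree's branch-node count,
then averaged over trees. No random-forest package in our dependency
stack implements this exact estimator, so the forest is implemented in
C++ inside the package; it draws from R's RNG, making rankings a pure
function of the seed. Ties in importance are broken lexically by feature
name.

Features with pooled pairwise |Pearson r| > 0.8 are then filtered greedily
from the top of the ranking (keep a feature iff it is below threshold
against everything already kept), at most 7 survivors enter the models,
and the baseline-IPSS covariate is exempt from the filter — it is a
clinical prior, not a competing radiomic feature.

Each bin is modeled with maximum-likelihood logistic regression (IRLS).
On complete separation the fit is retried with a ridge penalty of 1e-4 on
the non-intercept terms: coefficients stay finite and prediction ranking
is essentially unchanged. "Leave-one-out cross validation with 1000
bootstrapping iterations" admits two readings; the default here is
bootstrap-then-LOO — per iteration, a patient-level resample with
replacement (both classes enforced by redraw, at most 100 attempts),
leave-one-out over the resample's unique patients, one AUC per iteration
from the held-out scores — yielding a 1000-value AUC distribution
summarized by its median and 2.5/97.5 percentile interval (percentile CI;
no other flavor is identified). The alternative reading (LOO once,
bootstrap the held-out score pairs) is available behind
`method = "loo_boot_scores"`. AUC is the Mann-Whitney statistic with the
half-tie convention, and ROC curves come from the all-data LOO pass.

## The phantom cohort: what it emulates, what it does not

Each synthetic patient owns an RNG stream derived from the master seed and
the patient index, so cohorts are bit-reproducible and any patient can be
regenerated in isolation (also under parallel generation). The phantom is:

* a 64 × 64 × 32 grid at 0.9 × 0.9 × 2.0 mm — spacing-faithful to clinical
  CBCT but desk-scale (full 512 × 512 grids are supported, not default);
* an ellipsoidal ROI of ≈ 40 cc at full scale (semi-axes 20, 20, 24 mm,
  shrunk proportionally on smaller grids) — a typical prostate volume;
* speckle texture: a *persistent* per-patient Gaussian white-noise field —
  daily scans image the same anatomy — smoothed to a 4 mm correlation
  length, plus *fresh* unsmoothed imaging noise each fraction at 1/4 the
  texture contrast; base level 100, texture contrast 20 (arbitrary units).
  Freezing the anatomy field matters: with a fresh speckle realization per
  fraction, texture-matrix features fluctuate so much between fractions
  that only the first-order features carry usable delta signal. The
  `smooth` noise style adds a 1.5 mm low-pass, emulating the
  spatial-frequency attenuation of iterative reconstruction; `sharp`
  leaves the speckle as generated;
* per-fraction drift: at fraction k both the contrast multiplier and the
  inverse correlation length scale by (1 + drift·(k − 1)). Rising contrast
  is visible to the first-order features; shrinking correlation length is
  visible to GLCM contrast/NGTDM coarseness even after quantization
  (which is affine-invariant and would hide a pure amplitude change);
* drift rates: class 0 drifts at 0.010 ± 0.005 per fraction, class 1 at
  0.010 + effect × 0.005; `texture_effect_size` is therefore the class
  separation in drift-SD units. The default is 1.5 (moderate); 3.0 is the
  documented "strong" setting (latent class-separation AUC ≈ 0.98,
  leaving headroom for feature-estimation noise); 0 severs any
  image-outcome link, the null world;
* outcomes: the toxicity class is Bernoulli(prevalence 0.5); class-1
  patients receive a grade ≥ 2 during-treatment event at a BED onset
  uniform over the schedule (no onset distribution is documented for real
  cohorts, so uniform is the maximum-entropy choice) and a post-treatment
  grade ≥ 2 event with probability 0.6; grade-1 nuisance events occur in
  both classes. ΔIPSS is drawn with mean +2.5 for class 1 and −2.5 for
  class 0 (SD 3), clamped to the 0–35 IPSS range — worsening urinary
  scores co-occur with the faster-drifting class;
* fiducials: 3 gold markers, 1 mm radius rods spanning 5 mm axially,
  injected at ROI mean + 8 SD with four radial 6 mm spokes per slice at
  + 7 SD; ground-truth artifact voxels are returned so tests can assert
  perfect recall of the cleaning rule inside its 5 mm circle;
* schedules: 80 Gy/40 fx and 70.2 Gy/26 fx assigned 3:1, mirroring the
  usual mix of standard and moderately hypofractionated courses.

One deliberately *unphysical* touch: after composing texture and noise the
field is standardized against the in-ROI statistics and soft-clipped
through 2.5·tanh(x/2.5). This bounds every ROI voxel strictly inside 3
standard deviations of the ROI mean, so the 3σ artifact threshold
provably separates fiducial voxels (at +8 SD) from tissue — a property a
Gaussian field cannot have (≈ 0.1% of its voxels would always exceed 3σ).

The generator does **not** simulate projection-domain physics (scatter,
beam hardening), anatomical shape change, registration error, missed
imaging days, or the BMI/metal-prosthesis confounders excluded from real
cohorts. A green parameter-recovery test therefore establishes that the
pipeline detects a texture-drift signal of the stated size under the
stated noise — not that real prostate CBCT carries such a signal.

## Numerical choices and degenerate inputs

* Population (n) SDs everywhere in preprocessing; IBSI convention.
* Lloyd-Max: tolerance 1e-7 on MSE improvement, 500 iteration cap,
  deterministic uniform-partition initialization, empty bins keep their
  bin center as representative.
* Logistic IRLS: 50 iterations, step tolerance 1e-8, linear predictors
  clamped to ±30, ridge fallback 1e-4 on separation or divergence.
* Bootstrap: both-classes enforcement by redraw (≤ 100 attempts);
  iterations whose held-out set degenerates to one class return NA and are
  excluded from the median/CI; a bin whose every iteration degenerates is
  flagged unevaluable rather than aborting the run.
* Gini ties broken lexically; greedy correlation filter; half-open BED
  bins with inclusive upper edges.
* All tabular outputs are written with fixed 15-significant-digit
  formatting so reruns of the same config are byte-identical.

## Known limitations

* The 42-feature roster is reconstructed from the families and the names
  that appear in published selections; supplementary rosters vary across
  studies. The roster is centralized in `base_feature_names()`.
* Whether Collewet re-segmentation ran before or after fiducial removal in
  the original clinical pipelines is not documented; the default here is
  removal first (both orderings reachable via `preprocess_options()`).
* Real-data headline AUCs are not reproducible from synthetic cohorts and
  are deliberately not targets; the recovery tests check signal detection
  and null calibration, nothing else.
* The LOO-within-bootstrap validator is O(iterations × patients) logistic
  fits per bin; at the default 1000 iterations and 60 patients expect
  ~20 s per bin per endpoint on one CPU.
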