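---
title: "Statistical methods behind msidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind msidiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`msidiff` implements a five-step workflow for detecting differentially
abundant analytes in multi-sample mass spectrometry imaging (MSI)
experiments with complex designs — multiple conditions, paired tissues,
and repeated measurements per subject — together with the simulators used
to validate the workflow's operating characteristics. This vignette is the
package's own account of the statistics: the models and their assumptions,
the tunable parameters, what the simulators do and do not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The data model

A run is one sample's peak-picked image: pixel coordinates, an m/z axis,
and a pixel-by-feature intensity matrix in which absent peaks are stored
as zero — zeros are the only missing-value representation, mirroring the
sparse-matrix convention of peak-picked MSI containers. An experiment is a
set of runs on one shared m/z axis plus the design: per run, the subject
`i = 1..I` (biological replicate, nested in condition), the condition
`j = 1..J`, and the tissue `k = 1..K`. Run combination merges per-run m/z
axes by single-linkage clustering within a ppm tolerance, labels each
merged feature with the intensity-weighted mean m/z, and zero-pads
features absent from a run. No alignment tolerance is assumed by default:
it depends on the mass analyser and must be supplied.

# Step 1: normalization and ROI segmentation

## Censored-median normalization

Global methods (TIC, RMS) assume a stable baseline and few differential
features; reference normalization assumes a uniformly spiked standard.
Peak-picked data with heavy sparsity and large outliers breaks both, so
the recommended default drops the sparse zeros, right-censors each run's
nonzero intensities at the 95th percentile, and uses the censored median
as the run constant; runs are then scaled to the pooled median of all
runs' censored values. Numerical choices, each exposed as an argument:

* Quantiles use linear interpolation between order statistics (R's
  type 7), the dominant convention; documented so results are
  reproducible.
* "Right-censoring" clamps values to the threshold rather than deleting
  them (censoring retains the observation at the bound; deletion would
  change the median's breakdown behaviour). `censor = "drop"` provides
  the alternative.
* The pooled constant is the median of the pooled multiset of censored
  values (robust to unequal run sizes); `pooling = "median_of_medians"`
  provides the alternative.

The procedure is idempotent, and maps zeros to zeros. One subtlety: exact
scale *invariance* to rescaling a single run is impossible for any pooling
rule whose pooled constant depends on the runs — rescaling one run moves
the pooled median. What holds exactly, and what the tests assert, is
equivariance up to one global factor: every between-run ratio is
invariant, which is the quantity differential analysis consumes.

## ROI segmentation and the two failure modes

ROIs restrict analysis to comparable tissue regions. The package supports
external masks, univariate spatially regularized Gaussian-mixture
segmentation of one (or the pixel-wise mean of a few) marker features —
including nested segmentation, e.g. cartilage, then bone among the
remaining pixels, then background — and two multivariate methods (spatial
k-means and a spatially smoothed shrunken-centroids variant). The
multivariate methods exist mainly to demonstrate why they are
incompatible with downstream differential testing:

* *Double-dipping*: using feature intensities first to draw ROIs and then
  to test between those ROIs produces intensities that differ by
  construction; null-feature p-values are stochastically far below
  uniform.
* *Selection bias*: intensity-segmenting an ROI independently in each
  sample equalizes within-ROI means across samples and attenuates true
  between-condition differences.

Both are quantified by `run_segmentation_bias_study()`. Every data-driven
mask records the m/z values it consumed; `test_features()` and
`run_workflow()` refuse to test consumed features unless leakage is
explicitly allowed. At the preset effect sizes the between-condition test
saturates (nearly every differential feature is detected under any mask),
so the study reports the attenuation of the estimated condition difference
and the average p-value alongside sensitivity — the attenuation is the
robust signature of selection bias at desk scale.

The univariate segmenter is "sDGMM-lite": EM for a univariate Gaussian
mixture in which each iteration's per-pixel posteriors are smoothed with a
truncated Gaussian kernel (3 scales, boundary mass renormalized) and serve
as pixelwise mixing priors for the next E-step — the spatially-variant
finite-mixture formulation. Component moments are computed from the
un-diffused posteriors; smoothing only regularizes the label field.
Smoothing the posteriors *into* the M-step instead inflates the component
variances each iteration until the components merge, which is why that
formulation was rejected. The cited algorithm's Dirichlet adaptive
weighting is not implemented; the property the workflow relies on —
spatially regularized univariate segmentation — is preserved with a fully
specified algorithm. With `smooth_scale = 0` the priors stay global and
the algorithm is plain EM (tested against an independent EM oracle).
Initialization uses spread (5%/95%) quantiles with a seeded jitter; ties
in maximum-posterior assignment break toward the lower component index.

"SSC-lite" analogously replaces the cited shrunken-centroids method:
k-means initialization (farthest-point seeding under a fixed seed), class
centroids soft-thresholded toward the global centroid by `shrinkage_s`
pooled within-class SD units, assignment by spatially smoothed
nearest-shrunken-centroid posteriors, importance = the largest absolute
shrunken deviation per feature. Over-shrinkage collapses to a single
cluster and is flagged rather than an error.

# Step 2: filtering and aggregation

All Step-2 operations are blinded to condition labels and accounted for in
a per-feature ledger whose drop reasons sum exactly to the input count.

* Non-specific filter: a feature is dropped when its pooled nonzero mean
  AND SD both fall strictly below the 25th percentile of all features'
  means and SDs. Strict inequality is deliberate; a value equal to the
  percentile is kept.
* ROI sparsity filter: a feature is dropped when its fraction of zero
  pixels inside the labelled ROI exceeds 25% in any single run — the
  any-run rule, strict inequality, so exactly 25% is retained.
* Isotope clustering: edges join features separated by 1–3 times
  1.00336 Da (the 13C–12C spacing; charge 1 assumed, appropriate for
  MALDI peptides) within a ppm tolerance whose images are spatially
  similar (cosine on zero-filled images by default, threshold 0.7 —
  conventional values, not derived from data). Connected components are
  clusters; this classical mass-difference/colocalization clusterer
  replaces a deep-learning encoder that is out of scope here.
* Aggregation: each cluster is represented by its most intense member
  (ties to the lower m/z — usually the monoisotopic peak); the reduced
  matrix is a column subset, never a recombination.

# Step 3: per-feature models

The modelling unit is the ROI mean: for feature `f`, subject `i`,
condition `j`, tissue `k`, the mean intensity `Y_ijk` over the ROI pixels
of that run (zeros included under the zero-fill convention; an
exclude-zeros flag exists). Pixels of one sample are subsamples, not
biological replicates; treating them as replicates inflates the evidence
(demonstrated below). Three models, all with sum-to-zero fixed effects:

* **M1** (subset to one tissue): `Y = mu + Condition_j + e`,
  `e ~ N(0, s2_subj + s2)` — the pooled two-sample t-test.
* **M2** (subset to one condition): `Y = mu + Subject_i + Tissue_k + e`
  with `Subject ~ N(0, s2_subj)` — the paired t-test.
* **M3** (recommended): `Y = mu + Subject_i(j) + Condition_j + Tissue_k +
  (Condition x Tissue)_jk + e` — uses all observations and supports the
  interaction query.

Fitting is REML with the likelihood profiled over the variance ratio
`lambda = s2_subj / s2`, computed on cell-level sufficient statistics so
the same code fits ROI-mean models (16 observations) and
pixel-as-replicate models (tens of thousands) in O(#cells) per likelihood
evaluation. On balanced complete data the REML solution coincides with
the balanced-ANOVA closed forms (`s2 = MS_resid`,
`s2_subj = (MS_subj − MS_resid)/K`); the closed-form solution is handed
to the optimizer as a candidate so the equivalence holds to machine
precision, not optimizer tolerance. A subject variance estimated at the
zero boundary (ratio below 1e-6) is a singular fit: the model is refit
without the random effect, flagged, and downstream tests use the OLS
residual df. A random intercept with one observation per subject is
unidentifiable and is dropped up front.

Diagnostics per feature: Shapiro–Wilk normality of residuals and a
Levene-type test (ANOVA of absolute deviations from cell medians) at
`alpha_diag = 0.01`, plus studentized-residual outliers at |r| > 3. The
thresholds are declared decisions (the source workflow assessed plots
visually); exclusion of failing features from adjusted inference can be
disabled. Fewer than 8 residuals: not assessable, retained with a flag.

# Step 4: inference

Hypotheses are contrasts of population cell means: **A** between-subject
(condition 1 vs 2 within tissue 1), **B** within-subject (tissue 1 vs 2
within condition 1), **C** the interaction. On balanced data the test
statistics have closed forms — the SE is `sqrt(2 (s2_subj + s2) / I)` for
A, `sqrt(2 s2 / I)` for B (each subject is its own control, so the
subject variance cancels — the design reason within-subject comparisons
are more sensitive), `sqrt(4 s2 / I)` for C — with exact df `(I−1)J` for
M1-A, `(I−1)(K−1)` for M2-B, and `(I−1)J(K−1)` for M3-B/C. M3-A mixes two
mean squares, so its df uses the Satterthwaite approximation; on balanced
data the two-mean-square closed form
`(MS_s + (K−1) MS_r)^2 / (MS_s^2/df_s + ((K−1) MS_r)^2/df_r)`,
which always lies in `[min(df_s, df_r), df_s + df_r]`. Unbalanced data
and pixel models take the general path: GLS contrast variance plus a
delta-method Satterthwaite df from the numerical REML
variance-component covariance, floored at 1 and capped at the OLS
residual df (the approximation can be numerically unstable; the cap is
the guard). When A or B is requested from M3 the interaction is tested
first and a warning flag attached if significant, since main effects are
then not interpretable alone.

Multiplicity is controlled by Benjamini–Hochberg step-up adjustment,
applied separately per hypothesis family; NA p-values propagate without
counting toward the number of tests.

# Step 5: planning

The contrast SE is bounded by `Delta / (z_{1−alpha/2} + z_{1−beta})`,
giving `I >= 2 ((z_{1−alpha/2} + z_{1−beta}) / Delta)^2 V` with
`V = s2_subj + s2` (between-subject) or `s2` (within-subject), floored at
2; inverted, it yields the minimum detectable difference
`Delta = (z..) sqrt(2V/I)`. Under FDR control the per-test level is the
average alpha `(1 − beta_ave) q / (1 + (1 − q) m0/m1)`. Normal quantiles
are used as printed; they are slightly anti-conservative at small df
(at `I = 11`, achieved power ≈ 0.88 against a 0.90 target), so a
`t_refine` flag iterates with t quantiles and the achieved-power closure
test uses it. Variance inputs default to the median of the per-feature
REML components; the 75th percentile gives a conservative variant.

# The simulators (the stated world)

Both presets generate 100 × 100-pixel peak-picked images as

    Y[p, f] = baseline + effect(condition, tissue, ROI(p))
              + b[subject, f] + t[run, f] + pixel noise

with `b ~ N(0, s2_subj)` shared by a subject's runs, `t ~ N(0, s2_tech)`
a run-level technical offset, and the pixel noise a Gaussian random field
(white noise smoothed with a scale-2-pixel Gaussian kernel, re-standardized
— "moderate" spatial autocorrelation operationalized as the simplest
stationary field with a tunable correlation length). Intensities are
clamped at zero; baselines sit ≥ 5 SD above it so clamping is rare and the
Normal error model is undistorted. Every random stream is derived from the
master seed per subject, per run, and per (run, feature), so output is
reproducible and independent of iteration order. No intensity-dependent
missingness is simulated; a uniform dropout knob (default 0) exercises
sparsity when needed.

The run-level term deserves a note: the residual variance the ROI-mean
model estimates is realized at the run level, because pixel noise
averages away over thousands of ROI pixels (variance ~ s2_px · c / n for
correlated-area constant c ≈ 4π·scale²). A generator with pixel noise
only could not reproduce a stated technical:biological variance ratio in
ROI-mean estimates; `var_tech` is therefore the run-level component — the
"random difference specific to each sample" — and `pixel_noise_sd`
controls the within-image error separately.

* **Donut preset** (`sim1_config`): 8 single-tissue images in two
  conditions; a donut ROI of radii 20/38 pixels covering 32.8% of the
  image (about one-third); 3000 features of which features 1–100 are
  shifted +40 inside the ROI everywhere (ROI-defining), the last 500
  +30 inside the ROI in condition A only (differential), the middle 2400
  null. Unstated absolute scales chosen once: baseline 100, pixel-noise
  SD 10 (the +40 marker shift is then a clear 4-SD signal, realistic for
  a segmentation marker), run-level SD 2.
* **Variance preset** (`sim2_config`): 16 images from 2 conditions × 2
  tissues × 4 subjects per condition, each subject contributing both
  tissues; 300 features, half null, half with +2 condition and +2 tissue
  effects; `s2_subj = 1`, `s2_tech = 4` (the 4:1 technical:biological
  regime), pixel-noise SD 5. `swap_variance_regime()` exchanges the two
  components, preserving the total — the 1:4 regime. The true ROI is the
  whole image; the effects are tissue/condition-wide. Effect size +2 (one
  subject-SD) keeps power in the informative mid-range so the sensitivity
  orderings are visible rather than saturated.

What the generator does *not* emulate: mass error and isotope envelopes,
ion suppression, intensity-dependent missingness, multiplicative noise,
and raw profile spectra. A green test therefore establishes calibration
and recovery under Normal additive error with moderate autocorrelation —
the regime the downstream linear models assume — not robustness to
violations of it (the diagnostics step is the guard in practice).

# Validation studies

`run_variance_structure_study()` fits all models on ROI means and on
pixels under both variance regimes and tabulates TPR/FPR at unadjusted
P < 0.05, deliberately uncorrected. Expected directions, all asserted by
the suite: ROI-mean models near-nominal FPR; pixel-as-replicate M1/M2 FPR
far above nominal; the pixel M3 between-subject contrast near-nominal
(subject-level variance stays in the standard error no matter how many
pixels); within-subject TPR above between-subject TPR when biological
variance dominates; M3 at least as sensitive as the subset models.
`run_segmentation_bias_study()` quantifies the two segmentation failure
modes described above. Default study sizes are desk-scale reductions
(minutes, one CPU); the full presets are a config argument away.

# Known limitations

Spatial correlation within an ROI is ignored by the models (the ROI mean
absorbs it into the run-level residual; explicitly spatial per-pixel
models do not scale to these designs). No empirical-Bayes variance
moderation: with paired designs and ≥ 4 subjects its assumptions are more
restrictive than helpful. Normalization is per-run scaling only; no
batch-effect correction. Hypothesis C has no power formula (none is
established for the interaction in this framework). The imzML reader
supports processed-mode centroided data only.
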