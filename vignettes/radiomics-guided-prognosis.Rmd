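---
title: "Radiomics-guided deep-feature prognosis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics-guided deep-feature prognosis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pretreatment CT carries prognostic information about solid tumors: size,
margin sharpness, and the internal heterogeneity of attenuation all
correlate with outcome. Two families of image features compete for this
signal. Hand-crafted *radiomics* features (shape, intensity histogram,
co-occurrence and size-zone texture, margin descriptors) are interpretable
but limited to what was engineered. Features taken from a *frozen,
pretrained convolutional network* are richer but opaque, and training a
network from scratch is impossible at typical cohort sizes.

`radguide` implements a middle path: extract tens of thousands of frozen-CNN
activations from a small tumor patch, keep only those that are strongly
correlated with at least one radiomics feature (so each survives with an
interpretation attached), and build a sparse Cox risk score from the
survivors. The pipeline has five stages, each exposed as ordinary R
functions:

1. radiomics extraction (`extract_all`): 78 features per tumor;
2. deep-feature extraction (`extract_patch`, `extract_dl_features`):
   2.5D patches through a frozen backbone;
3. guided selection (`correlation_screen`): Pearson screening with
   Bonferroni control;
4. risk modeling (`cox_lasso_fit`, `risk_score`, `median_stratify`):
   L1-penalized Cox regression and median stratification;
5. evaluation and interpretation (`stratify_evaluate`, `associate`).

A synthetic phantom-cohort generator (`generate_cohort`) plants known
prognostic structure so that every stage — including the end-to-end
pipeline — is testable without clinical data.

# The risk model

For patient $i$ with selected (z-scored) features $x_{ij}$ and Cox-LASSO
coefficients $\beta_j$, the risk score is the relative hazard at time zero,

$$\mathrm{RS}_i \;=\; h(X_i, 0) \;=\; h_0(0)\, \exp\!\Big(\sum_{j=1}^n x_{ij}\,\beta_j\Big),$$

with the baseline constant fixed at $h_0(0) = 1$; being a positive
constant, it cancels in every downstream use (median stratification,
concordance, log-rank), which the test suite checks explicitly. Risk
groups are defined by the *training-cohort median* score; a score exactly
at the cutoff is assigned to the low-risk group. Groups are compared with
Kaplan--Meier curves, the two-group log-rank test, a Wald hazard ratio
from an unpenalized Cox fit on the group indicator, and Harrell's
concordance index of the continuous score.

## Cox-LASSO and penalty selection

Coefficients are estimated by L1-penalized Cox partial likelihood
(Breslow tie handling, via `glmnet`), with the penalty chosen by 5-fold
cross-validated grid search over 50 log-spaced values spanning four
decades below the data-derived maximal penalty. Folds are event-stratified
and fully seeded; a fold that draws no events is redrawn once with a
logged sub-seed. An outer 5-fold loop repeats the search on outer-training
subsets purely to report penalty-choice stability. The selection metric is
the *held-out Breslow partial log-likelihood*; the concordance index was
the alternative, but partial likelihood is the quantity the model
optimizes, is cheaper, and behaves better with few events per fold, so it
was adopted. The final model is refit on the full training set at the
chosen penalty.

Two numerical guards matter at desk scale. First, when the feature count
far exceeds the event count, the unconverged tail of the penalty path is
replaced by the most-penalized converged solution (the held-out likelihood
is monotone-worsening there, so this never changes the selected penalty in
practice). Second, `glmnet` requires at least two columns, so a
single-feature design is padded with an inert zero column that the L1
penalty leaves at exactly zero.

## Evaluation conventions

* Log-rank: standard two-group statistic on one degree of freedom; the
  reported group-difference p-value is the log-rank p. The hazard-ratio
  p-value (Wald) is reported alongside.
* Harrell's C: a pair is usable when the shorter follow-up ends in an
  event and the times differ; score ties count 0.5. Tied event times are
  not comparable. An exhaustive pair-enumeration oracle and
  `survival::concordance` cross-check this in the tests.
* ICC(2,1) (two-way random effects, absolute agreement) and Cohen's kappa
  are provided for reproducibility analyses of repeated feature
  measurements and repeated ROI masks.

# The 78-feature radiomics roster

The roster is a fixed, documented convention: 14 shape, 18 first-order,
24 GLCM, 16 GLSZM and 6 margin features, concatenated in the order given
by `radiomics_feature_info()`. The texture and first-order definitions
follow the IBSI-consistent formulas used by the common extractors; every
feature is verified in the test suite against an independently coded
brute-force oracle on toy ROIs.

Conventions, with their defaults:

* **Discretization** — 32 equal-width bins over the ROI intensity range
  (range-relative, so all texture features are invariant to adding a
  constant to the volume). Configurable via `radiomics_config()`.
* **GLCM** — voxel distance 1, the 13 unique 3D directions, symmetrized
  and normalized per direction; feature values are computed per direction
  and then averaged (feature-level averaging; matrix-level averaging is
  the other defensible reading and gives slightly different values).
  Entropies are in bits.
* **GLSZM** — zones are 26-connected components of equal gray level; the
  matrix conserves mass (`sum(size * count)` = ROI voxel count).
* **Shape** — voxel-based: volume is voxel-counted, surface area counts
  exposed voxel faces (which overestimates a smooth surface by a factor
  approaching 1.5 — sphericity of a rasterized sphere is therefore near
  2/3, consistently so across the cohort), axis lengths are
  `4 * sqrt(eigenvalue)` of the voxel-center covariance, and the maximum
  2D/3D diameters are exhaustive pairwise distances (over per-plane convex
  hulls / surface voxels). No installed R package provides 3D marching
  cubes, and a consistent voxel-face convention serves the comparative
  purpose equally well.
* **Margin** — at up to 64 boundary voxels (foreground voxels with a
  background face-neighbor), intensity profiles are sampled by trilinear
  interpolation along the outward ray from the mask centroid over ±5 mm.
  Each profile is reduced to the maximal finite-difference slope of its
  empirical intensity CDF; the six features are the mean, SD, skewness,
  kurtosis, median and IQR of the per-profile slope distribution. This is
  a declared, testable design: the original margin-CDF features were
  described only by name, so the package fixes a concrete geometry
  (centroid rays) and summary set that exposes the named skewness and
  kurtosis statistics.
* **Normalization** — z-scores use the training-cohort mean and *sample*
  SD (n−1); test and validation tables are always transformed with
  training parameters. Zero-variance features are dropped with a message,
  never propagated as NaN.
* No resampling to isotropic spacing is performed by default (the
  intended inputs are thin-slice reconstructions on near-isotropic grids);
  all physical quantities respect the stored voxel spacing.

# Deep features from frozen backbones

## Patch protocol

The 2.5D patch takes the three consecutive axial slices centered on the
slice of largest tumor area (ties go to the smallest index; at the volume
boundary the edge slice is replicated) and crops a 128×128 in-plane window
centered at the rounded (`floor(x + 0.5)`) in-slice mask centroid,
padding out-of-grid regions with the lower clip bound. Intensities are
clipped to the lung window `[-1700, 300]` HU (level −700, width 1500,
extended by half a width each side) and min-max scaled to [0, 1] with
these fixed bounds, so the scaling is content-independent. The three
slices go to the three input channels (slice-per-channel rather than
replication of the center slice). Backbones that want larger inputs get
corner-aligned bilinear upsampling (`resize_patch`), which preserves
corner values and linear ramps.

## Backbones and dimensions

Four backbones are registered; none ships weights. `weights = "random"`
draws a deterministic He-normal initialization from the seed, or an `.rds`
weight list (saved from `build_extractor()$weights`) may be supplied.

* `yolo_v3_l107` — the full detection backbone graph (residual
  feature extractor plus the three-scale head with routes and nearest
  upsampling), truncated at the last 255-channel 1×1 convolution at the
  finest (1/8) scale. A 128×128×3 input yields 255×16×16 = **65,280**
  flattened features, which the acceptance suite verifies by an actual
  forward pass.
* `vgg19_features` — the 16-convolution stack with the classifier
  removed; the torchvision-style adaptive 7×7 average pool is retained,
  so the dimension is 512×7×7 = **25,088** for any admissible input size.
* `densenet201_features` — the four dense blocks (6/12/48/32,
  growth 32) with transitions, ending at the post-activation 1920-channel
  map; a 256×256×3 input yields 1920×8×8 = **122,880** features. (A
  printed value of 122,800 circulates for this configuration; it is not
  consistent with the architecture, and the package reports the computed
  dimension.)
* `random_cnn_test` — a small seeded stride-2 stack (16/32/32/32
  filters, bias-free ReLU) used throughout the tests so that nothing ever
  downloads weights. Its random initialization is *scattering-style*: the
  first layer's filters are mean-centered (random band-pass analysis) and
  deeper layers use nonnegative weights (energy pooling). A rectified
  band-pass cascade responds to the amplitude and scale of intra-tumoral
  texture the way pretrained early layers do, which plain He-random
  stacks largely do not; without this the test backbone would be
  near-blind to the very property the synthetic cohorts plant.

`output_dim()` computes every dimension from the layer graph without
instantiating weights, and the tests assert it equals the length of the
actually extracted vector. Flattening is column-major (row fastest, then
column, then channel) with stable names `<prefix>_Latent_<index>`.

# Guided selection

All deep × radiomics feature pairs are correlated (Pearson) on the
*training cohort only*, both tables z-scored with training parameters. A
deep feature is retained when its best association has `|r|` strictly
greater than the threshold (default 0.4, configurable; 0.3 and 0.5 are
the standard sensitivity settings) *and* a Bonferroni-corrected p-value
below 0.05. The Bonferroni family is the full deep × radiomics pair set —
the most conservative reading — with zero-variance deep features (dead
units under frozen weights) excluded beforehand and counted. P-values use
the exact t-transform `t = r sqrt((n-2)/(1-r^2))` on n−2 degrees of
freedom. The screen stores per-pair values, the sparse above-threshold
pair map, and full association profiles for the retained features, so the
interpretation stage never recomputes a correlation.

Interpretation (`associate`, `category_proportions`) reports, per selected
deep feature, its above-threshold radiomics associates sorted by |r|
(signed values preserved), the count of associates significant at
*uncorrected* p < 0.05 (deliberately distinct from the Bonferroni screen,
and labeled as such), and the composition of its associates across the
five categories.

# The synthetic cohort generator

`generate_phantom` renders one tumor: a sphere of radius `tumor_radius_mm`
at `tumor_level` pseudo-HU on a `background_level` grid, blurred with a
Gaussian of SD `margin_width_mm` (the margin), carrying an intra-tumoral
Gaussian texture field (white noise smoothed to correlation length
`texture_correlation_length_mm`, rescaled to SD `texture_sd`), plus i.i.d.
voxel noise. The smoothing kernel is truncated at 4σ and renormalized, so
the plateau is *exactly* `tumor_level` wherever the kernel support lies
inside the mask — the basis of an exact test. All randomness derives from
one integer seed through fixed sub-seed streams (`derive_seed`), so any
stage can be regenerated independently and identical specs are
bit-identical.

`generate_cohort` draws per-patient phantom parameters uniformly from
stated ranges and samples survival from a proportional-hazards model with
exponential baseline: `T ~ Exp(h0 * exp(lp))`, where the linear predictor
is a weighted sum of cohort-standardized planted properties. Censoring is
the minimum of a 60-month administrative cap and, for a 10% dropout
fraction, a uniform dropout time. The ground-truth linear predictor is
returned for recovery tests.

Study conditions (the generator defaults, chosen once):

* grid 40³ voxels at 1 mm, radius 6–12 mm, texture correlation length
  1–3 mm, texture amplitude 20–200 HU (homogeneous solid nodules up to
  strongly mixed attenuation), margin blur 0.5–2.5 mm, background
  −800 HU, tumor 0 HU, noise 10 HU;
* strong heterogeneity effect `beta = 3` on the standardized texture
  amplitude, baseline hazard 5e-4 per month — together with the censoring
  scheme this yields roughly 20% observed events over follow-up (checked
  once at n = 20,000 and fixed). Null cohorts (`betas = 0`) keep the same
  ~20% event rate by raising the baseline hazard to 4e-3, so the null
  isolates the absence of an image effect rather than event scarcity.

The sizes are desk-scale by design: a 200-patient cohort generates,
extracts and models in well under a minute, which is what makes the
20-seed end-to-end recovery experiments in the test suite practical.

What the generator does **not** emulate: lung anatomy (airways, vessels,
pleura), non-spherical or lobulated shapes, solid/ground-glass component
structure, scanner and reconstruction-kernel effects, or informative
censoring. Passing the planted-effect tests therefore shows that the
pipeline's plumbing and statistics recover a known image-encoded hazard
under clean conditions — not that any particular clinical effect size is
attainable on real CT.

# Degenerate inputs and edge rules

* Constant ROI → all voxels in bin 1; first-order entropy 0, uniformity 1;
  skewness/kurtosis of a degenerate distribution defined as 0.
* Single-voxel ROI → GLCM is an error ("degenerate ROI": no voxel pairs);
  shape diameters 0, elongation/flatness defined as 1.
* Profiles with fewer than two distinct values have no CDF slope; fewer
  than 8 usable margin profiles is an error ("margin undersampled");
  profiles leaving the grid are clipped with a warning.
* All-equal risk scores → everyone low-risk; C-index of tied scores is
  0.5 by the tie rule.
* No events in one group → the hazard ratio is reported non-estimable
  with a warning rather than a divergent number.

# Known limitations

* The shape surface area (and hence sphericity) uses the voxel-face
  convention; values are systematically offset from mesh-based extractors
  though monotone with them.
* The margin feature geometry (centroid rays) degrades for strongly
  non-convex masks, where outward normals and centroid rays diverge.
* Random-weight backbones are stand-ins for pretrained ones: dimensions,
  determinism and pipeline behavior are faithful, but feature *quality*
  with real weights will differ.
* With very few events (< ~10 in a fold) the penalty search grows noisy;
  the implementation guards the degenerate cases but small-cohort results
  should be read accordingly.
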