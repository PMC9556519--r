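---
title: "Hybrid QC: models, simulators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid QC: models, simulators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybridqc)
```

# The problem

Expert visual quality control (QC) of diffusion MRI does not scale: a
thorough review of one participant's preprocessed dMRI takes minutes, and
modern pediatric studies enroll thousands of participants whose head motion
makes QC decisions consequential for every downstream analysis. The hybrid
QC paradigm spreads the expert signal in three amplification steps:

1. a small **gold standard** subset is rated by a panel of experts on a
   five-level ordinal scale (-2 definitely fail ... +2 definitely pass);
2. the expert labels are **amplified** to a much larger subset by
   gradient-boosted classifiers trained on cheap signals: binary pass/fail
   ratings from community scientists and automated data-quality metrics;
3. the amplified labels train an **image-based 3D convolutional network**
   that scores every current and future participant directly from the b=0 +
   DEC-FA image, with no rating collection at all.

`hybridqc` implements each step, the reliability statistics that justify
them, integrated-gradients interpretation of the image model, leave-site-out
generalization experiments, and a QC-cutoff sensitivity analysis of a
benchmark age-prediction task. Everything runs on synthetic cohorts produced
by the package's own generators, so the full pipeline is testable offline.

# Latent-quality cohort model

All simulators hang off a single latent construct: per-participant scan
quality $q \in [0,1]$.

* $q \sim \mathrm{Beta}(2.5, 1.2)$ by default, giving the predominantly
  passing cohorts typical of curated studies (pass fraction
  $P(q \ge 0.5) \approx 0.79$); the shape parameters move the label balance
  monotonically.
* Age (uniform on 5-21 years) is linked to $q$ through a Gaussian copula
  with correlation 0.31 by default, reproducing the well-known direct
  age-quality association in pediatric imaging (younger children move
  more). Sex and site are independent of $q$ by construction, so any
  site/sex effect a model finds downstream is spurious by design.
* `true_label` is $\mathbf{1}[q \ge 0.5]$.

The ground-truth $q$ is what every estimator in the pipeline is implicitly
trying to recover; tests therefore phrase recovery as rank correlation with
$q$.

## Expert ratings

Expert $r$ reports `findInterval(q + bias_r + noise, c(.2,.4,.6,.8)) - 2`,
i.e. all raters share the instrument's cutpoints and differ only by a bias
($\sigma = 0.04$) and per-rating noise ($\sigma = 0.12$). The noise default
is calibrated once so the simulated panel's mean pairwise quadratic-weighted
kappa falls in the 0.5-0.8 "substantial agreement" regime reported for
expert dMRI panels; we do not tune it further. Aggregation rescales the
panel mean to $[0,1]$ via $(\bar r + 2)/4$, binarizes at 0.5, and assigns
the 0.2-wide ordinal bands (0-0.2 definitely fail, ..., 0.8-1 definitely
pass).

## Community ratings

Community raters see slice views and give binary pass/fail votes. Rater $r$
has a drawn sensitivity (Beta(9, 2.2)) and specificity (Beta(4, 3)) applied
to `true_label`; an *optimism* parameter (default 0.45) moves every rater's
pass probability toward 1, reproducing the observation that community
raters are systematically less conservative than experts. Views are
conditionally i.i.d. given (rater, participant) — the package does not model
inter-view structure because no quantitative description of it is
available. Assignment is sparse: 40 raters x 10 views at 50% coverage gives
roughly 200 ratings per participant, the density regime of large community
QC campaigns.

## Automated quality metrics

The 31-column metrics table follows the ImageQC schema: 14 informative
motion/quality summaries plus 17 acquisition descriptors that are constant
within site (voxel sizes, grid dimensions, direction counts, maximum
b-value). The informative columns are monotone transforms of $q$ plus
noise, with the empirically observed sign structure: neighboring-DWI
correlation rises with quality; relative translation/rotation, framewise
displacement and outlier-slice counts fall. The default noise multiplier
(1.75) is calibrated so metric-vs-expert-score Pearson correlations land
near |0.6-0.8| — informative but far from deterministic — because the
scientific point of the amplification step evaporates if the metrics alone
already decide every case.

## Phantom volumes

`generate_volume()` builds a 4-channel phantom: a smooth head-like b=0 blob
plus three tube-shaped "bundles" whose DEC-FA energy concentrates in the
channel matching their orientation (lateral -> x, anterior-posterior -> y,
superior-inferior -> z). Quality degradation has two components, both
scaling with $1-q$: an alternating-slice gain $1 \pm 0.35(1-q)$ along the
inferior-superior axis of the b=0 channel (a one-parameter model of the
banding artifact produced by between-volume motion), and attenuation plus
axial blur of the DEC-FA channels. These phantoms capture exactly the
features the image QC model is supposed to use — banding and coherent,
correctly-oriented bundles — and nothing else: no anatomy, no eddy-current
geometry, no susceptibility distortion. A classifier that separates them
has learned banding-vs-structure, not dMRI; passing the smoke test is
evidence the training machinery works, not that the architecture reaches
any particular accuracy on real data.

## Bundle profiles

FA and MD are sampled at 100 nodes along 24 bundles (8 bilateral pairs + 8
callosal segments). Each (bundle, metric) has a fixed template of 1-3
Gaussian bumps on a common baseline — real templates are empirical, but only
the existence of node structure matters here. Three mechanisms tie profiles
to the latent quality:

* **Flattening**: deviations from the profile mean shrink by
  $1 - 0.8(1-q)$, making low-quality profiles artifactually homogeneous.
* **Apparent-age corruption**: the log-age entering the maturation trend is
  shifted by a per-participant draw with sd $0.5\,\min(1, 2(1-q)^2)$
  log-years. The quadratic severity concentrates damage in clearly bad
  scans. This is the mechanism that makes QC screening *matter* for
  inference: a corrupted apparent age is irreducible error. An earlier
  design that added learnable whole-profile offsets failed as a
  QC-sensitivity testbed precisely because the regressor could exploit the
  artifact-age correlation — itself a nice demonstration of why QC-correlated
  artifacts produce replicable but invalid effects.
* **MD bias**: a small downward MD shift proportional to $1-q$, mimicking
  motion-corrupted scans "looking older".

The age trend is zero-mean across nodes (maturation reshapes a profile
rather than shifting it wholesale), so flattening genuinely destroys age
information. Site effects are additive and multiplicative per (site,
metric). The negative control for the sensitivity analysis sets
`flatten = 0, md_bias = 0, distort = 0`, severing every quality-profile
link.

# Reliability statistics

Quadratic-weighted Cohen's kappa is computed from the contingency
proportions with $w_{ij} = (i-j)^2/(k-1)^2$ on the **fixed** five-level
scale ($k = 5$) even when a sample does not realize all levels: the scale
belongs to the instrument, and dropping unobserved levels would make kappa
depend on the sample. Pairs where both raters are constant and identical
are undefined and returned as `NA` with a warning, never silently as 1.

ICC3 and ICC3k (two-way mixed, consistency) come from the ANOVA mean
squares; confidence intervals use the Shrout-Fleiss F bounds. ICC3k is the
panel-mean reliability (fixed panel rates everyone); ICC3 is the
single-coder variant appropriate when one coder's scores must generalize —
which is exactly the situation when the amplification model becomes "a
seventh expert". Model scores enter that ICC as continuous $[0,1]$ values
next to the rescaled expert means, without re-discretization: the released
score is continuous, and discretizing would throw away exactly the
resolution the ICC is meant to assess. The test suite pins both statistics
to independent from-definition oracles (pairwise-enumeration kappa, `aov()`
mean squares) and to the Spearman-Brown identity
$ICC3k = k\,ICC3 / (1 + (k-1)\,ICC3)$ at $10^{-10}$.

Pairwise kappa uses pairwise-complete ratings per pair (rather than a
global listwise filter): it maximizes the data each pair sees and matches
how missing ratings arise in practice.

# Label amplification

Features are assembled per mode: `q` = the 31 metrics; `f` = one column per
community rater holding that rater's mean rating for each participant
(missing where unrated); `q+f` = both. The per-rater encoding is what lets
the tree ensemble weight raters by their reliability; missingness is left
explicit because the tree learner handles it natively and imputation would
blur the distinction between "rated fail" and "not rated".

`fit_calibration()` runs repeated stratified K-fold cross-validation (3
splits x 2 repeats), tunes each fold's gradient-boosted classifier by
randomized search over a small grid (depth, learning rate, rounds,
subsampling) on an inner stratified holdout, and keeps all six fold models
as a voting ensemble weighted by held-out-fold ROC-AUC:
$p = \sum_m w_m p_m / \sum_m w_m$. Randomized search stands where the
original workflow used a Bayesian optimizer; the search strategy is not the
scientific content, and the budget is configurable. Out-of-fold
predictions are stored so the reported cross-validated AUC can always be
recomputed from raw material.

Global feature importance is the mean absolute Shapley value per feature:
tree-path Shapley values for the boosted members (combined with the voting
weights), and a permutation-sampling estimator for arbitrary models. The
sampling estimator marginalizes exactly over the supplied background at
every step, so only the permutation order is stochastic and additive models
are recovered exactly; the suite checks it against full subset enumeration
on small feature sets.

# The image QC network

Four convolutional blocks (3x3x3 kernels, ReLU, 2x2x2 max-pool, batch
normalization) with 64/64/128/256 filters; global average pooling; for the
metrics-augmented variant, the standardized 31-vector joins the pooled
features and the concatenation is batch-normalized; two fully connected
layers (512, 128) each followed by 40% dropout; a single sigmoid unit.
With 4 imaging channels and 31 metrics this is exactly **1,438,783**
trainable parameters (batch-norm scale and shift count; running statistics
do not) — the count is pinned in the test suite and is invariant to the
input extents because global average pooling decouples the dense head from
the grid size.

Numerical/design notes:

* Convolutions are zero-padded ("same"). An unpadded 3x3x3 stack cannot
  survive four pool-2 halvings from any desk-scale grid (it needs extents
  of ~38+), while the parameter count is padding-invariant; padding is the
  only choice under which the module's declared 32^3 default is coherent.
  Extents below 16 are rejected up front.
* The engine is the package's own: im2col/col2im and pooling kernels in
  C++, convolutions as BLAS matrix products, activations stored as
  voxels-by-channels matrices so batch statistics are column statistics.
  Gradients flow only through pooling argmax positions, which keeps the
  backward pass sparse. Every layer's gradient is verified against central
  finite differences in the suite.
* Batch normalization uses batch statistics in training and exponential
  running statistics (momentum 0.99, eps 1e-3) at inference; the imaging-
  only variant keeps the post-pooling batch norm so the two variants differ
  only by the metrics path.
* Training: Adam at 1e-4 on binary cross-entropy; learning rate halves when
  the validation loss plateaus for more than two epochs; training stops
  when it fails to improve by more than 0.001 for twenty consecutive
  epochs; best-validation weights are restored. The schedule lives in a
  pure state machine (`monitor_update`) so the rules are unit-testable on
  constructed loss traces. Continuous amplified scores are binarized at 0.5
  before entering the loss.
* Replicate training over seeds is supported; multi-replicate prediction is
  the arithmetic mean of probabilities — the simplest symmetric combination,
  chosen because no combination rule is externally specified.

The smoke task trains the full architecture on 200 phantoms at 32^3 for 2
epochs (the task saturates after one; the ceiling of 10 in the acceptance
checks is never needed) and asks for held-out ROC-AUC >= 0.85. On a single
CPU this takes a few minutes; it is a scaled-down analogue of the published
full-data performance, not a reproduction of it.

# Integrated gradients

Attribution of the sigmoid output along the straight path from a black
(all-zero) baseline, with a midpoint Riemann rule: at equal step count the
midpoint rule roughly halves the discretization error of one-sided rules,
and for linear models any rule is exact (the suite asserts exact
$w_i x_i$ recovery). The completeness residual
$|\sum_i a_i - (F(x) - F(b))|$ is recorded in the map's metadata; at
`m_steps = 128` it stays below 1% of $|F(x) - F(b)|$ on the smoke network.
Because the integrand is only piecewise smooth (ReLU kinks, pooling argmax
switches), per-volume gaps can wiggle between step counts; monotone decay
is asserted on the mean over volumes. We attribute the probability rather
than the logit: the released scores are probabilities and the sign
convention ("positive = evidence toward pass") refers to them. For the
metrics-augmented model the black baseline zeroes the metrics vector too.

Display masking keeps voxels whose |attribution| strictly exceeds 98% of
the image's peak. A constant-magnitude map therefore renders entirely —
every voxel ties the peak — and an all-zero map yields an empty mask without
dividing by zero.

# Evaluation and site generalization

ROC-AUC is the pairwise-concordance probability with ties counted half
(computed via the rank-sum identity, pinned to a brute-force pair
enumeration in tests); balanced accuracy is the mean of sensitivity and
specificity at the 0.5 threshold used throughout. The default leave-site-
out plan holds out each 3T-site combination: CBIC+CUNY/RU, CBIC/RU+CUNY,
RU+CUNY/CBIC, RU/CBIC+CUNY, with 20 replicates for the metrics-calibration
family and 8 for the CNN family by default (both configurable; the suite
uses 2-3 replicates to stay inside a single-CPU budget). Because the
synthetic metric generators have no site-dependent quality structure,
held-out-site AUC should match within-site AUC — and does; injecting a
"this scanner makes everything look clean" shift into a held-out site
hides its failures from the trained model and collapses balanced accuracy,
which is the qualitative failure mode the protocol exists to detect.

# QC-cutoff sensitivity

The age-prediction benchmark uses the 4,800-feature bundle-profile table
(24 bundles x {FA, MD} x 100 nodes), median imputation for missing
bundles, site harmonization, and a gradient-boosted regressor on
log-transformed age under repeated K-fold cross-validation (5x5),
back-transforming predictions so $R^2$ is on the year scale. Natural log is
used; only monotonicity matters. The cutoff grid is 0 to 0.95 in steps of
0.05 (20 values); cutoffs that leave fewer participants than the fold
scheme needs are reported as unavailable rather than silently re-folded.

Harmonization offers two estimators behind one interface: a transparent
per-site location-scale adjustment (the default in the package's own
experiments, and trivially verifiable: a pure location shift between sites
is removed to machine precision) and the parametric empirical-Bayes
estimator, delegated to `sva::ComBat`, which shrinks site effects across
features and is preferable for small sites.

Regressor defaults are fixed and recorded with the results: depth 3, eta
0.15, subsample 0.8, `colsample_bytree = 0.1`, exact splits, 40 rounds.
The aggressive column subsampling is what makes 500 fits on a 4,800-column
table tractable on one CPU; with heavily redundant profile features it
costs little accuracy. The experiments in the acceptance script run a
260-participant cohort with QC scores mapped through a sharp logistic
(`plogis(12 (q - 0.625))` plus small noise), emulating the confidently
bimodal score distribution an image classifier produces — a low-scoring
cluster that the very first cutoff removes. On the quality-dependent
profiles the $R^2$ curve reproduces the canonical shape: a jump at the 0.05
cutoff, a gentle rise, and a collapse at extreme cutoffs once the retained
sample shrinks below ~70; under the negative control the curve is flat.

# Known limitations

* The phantoms and profile generators encode only the mechanisms the
  pipeline is designed to detect; green tests certify the machinery and the
  statistical logic, not performance on real dMRI.
* The conv-net engine is CPU-bound and double-precision; it is sized for
  desk-scale experiments (tens of seconds per epoch on 200 phantoms at
  32^3), not for training on full-resolution cohorts.
* The CNN arm of the site-generalization protocol is implemented but
  expensive at replicate counts matching the published protocol; the
  packaged experiments exercise the metrics-calibration arm.
* Probability calibration of the voting ensemble (Platt/isotonic) is out of
  scope; the voting weights are used as-is.

# Problem sizes used by the packaged experiments

Gold standard n = 200 with 6 experts; amplification cohorts n = 600 with
40 community raters; CNN smoke task n = 200 phantoms at 32^3, 2 epochs;
sensitivity sweep n = 260 with 5x5-fold (positive arm) and 5x2-fold
(negative control) cross-validation; site generalization n = 500 with 2-3
replicate ensembles per split. These sizes were chosen as the smallest
cohorts at which the relevant effects are unambiguous.
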