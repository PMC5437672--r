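---
title: "Methods: peritumoral DCE-MRI radiomics for response prediction"
author: "periradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peritumoral DCE-MRI radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

Pathological complete response (pCR) to neoadjuvant chemotherapy —
the absence of residual invasive tumor at surgery — is a strong
surrogate for long-term outcome in breast cancer, but it can only be
observed after months of treatment. This package implements a
pretreatment prediction pipeline built on dynamic contrast-enhanced
MRI (DCE-MRI): serial T1-weighted volumes acquired before and at
2, 3.5, 5, 6.5 and 8 minutes after contrast injection. Its central
hypothesis is that response signatures live not only inside the
lesion but in the *peritumoral* tissue ring immediately around it,
where angiogenic activity, lymphovascular invasion and immune
response alter local enhancement texture.

The pipeline turns each scan into 1980 radiomic features plus 15
pharmacokinetic (PK) features, discovers a compact response-associated
feature set with an iterated mRMR protocol, checks that the selected
features induce response-aligned structure via consensus clustering,
and quantifies predictive value with five standard classifiers under
repeated cross-validation and holdout testing. Because no patient
cohort is distributed with the package, a digital-phantom generator
reproduces the study design (cohort sizes, phase timing, class-linked
texture differences) so that every stage is exercised end to end.

# Region geometry

The peritumoral region is obtained by slice-wise 2D morphological
dilation of the tumor mask with a disk structuring element of
Euclidean radius 5 pixels (center included), minus the tumor. Across
in-plane pixel spacings of 0.5–1.0 mm this one fixed rule spans a
physical ring extent of 2.5–5 mm, matching the intended
"2.5–5 mm depending on pixel size" design. The dilation is 2D rather
than 3D because slice spacing (0.9–3 mm) is strongly anisotropic and
all texture windows are in-plane; consequently no ring voxel ever
appears on a slice without tumor. The ring is clipped at the image
grid and no air/chest-wall exclusion is attempted (the package has no
anatomy model); users with anatomical masks can intersect them with
`peritumoral_ring()` output.

# Texture maps

All 99 descriptor maps are computed per 2D slice with mirror-padded
borders.

* **Laws energy measures (25).** Separable 5×5 filters from all
  ordered pairs of the classical 1D kernels L5 = (1,4,6,4,1),
  E5 = (−1,−2,0,2,1), S5 = (−1,0,2,0,−1), W5 = (−1,2,0,−2,1),
  R5 = (1,−4,6,−4,1). Filtering is implemented as correlation; on a
  constant image the L5L5 response is 16² = 256 times the level and
  all other maps vanish (zero-sum kernels).
* **Gabor magnitudes (48).** Six frequency parameters
  f ∈ {0, 2, 4, 8, 16, 32} × eight orientations. The frequency is
  read as cycles per 64-pixel reference window, the isotropic
  Gaussian envelope has one-octave bandwidth (σ ∝ wavelength), and
  kernels are truncated at 2.5σ (capped so they fit the slice). Two
  printed conventions required a decision:
  * `f = 0` has no oscillatory meaning; it is implemented as the
    normalized low-pass Gaussian envelope at the unit-frequency
    scale, the natural zero-frequency limit of the bank.
  * The orientation grid defaults to the uniform 22.5° lattice
    0–157.5°; a variant ending at 167.5° is available via
    `gabor_theta_grid("printed")`.
  Filters with f > 0 are DC-corrected, making their magnitudes
  invariant to intensity offsets.
* **Haralick statistics (13).** Per pixel, the slice (quantized to 64
  gray levels by min–max scaling over tumor + ring voxels of that
  slice) contributes a symmetric gray-level co-occurrence matrix over
  unit offsets in the 0°, 45°, 90° and 135° directions within a 5×5
  window, normalized to sum 1. The 13 classical statistics use
  1-based level indices and natural logarithms; correlation is 0 when
  a marginal variance vanishes, sum variance is centered on sum
  average, and the two information measures of correlation guard
  their degenerate denominators (0 when the marginal entropy is 0).
  64 levels is the common GLCM default; fewer levels saturate the
  short 5×5 windows, more levels make them vacuous.
* **CoLlAGe statistics (13).** Gradients by central differences; each
  pixel's dominant orientation is the principal singular vector of
  the gradient samples in its own 5×5 window (computed from the 2×2
  structure matrix in closed form), mapped to [0, π) and quantized
  into 64 uniform bins (windows with identically zero gradients take
  bin 0 by convention). The binned orientations then go through the
  same windowed co-occurrence machinery. A planar ramp has a single
  dominant orientation everywhere and therefore zero CoLlAGe entropy;
  disordered gradient fields raise it monotonically.

Map ordering is fixed — Laws (row-major), Gabor (frequency-major),
Haralick, CoLlAGe — giving stable, reproducible column identities.

# Pharmacokinetic baseline

Tissue concentration follows the standard Tofts model
$C_t(t) = K^{trans}\int_0^t C_p(u)\,e^{-k_{ep}(t-u)}\,du$ with
$v_e = K^{trans}/k_{ep}$ the extravascular-extracellular volume
fraction. (Some sources gloss $v_e$ as "tumor volume"; the package
uses the standard Tofts definition.) Since no measured arterial input
function is available, $C_p$ is the population bi-exponential
(Weinmann-type) curve with amplitudes (3.99, 4.78) kg/L and decay
rates (0.144, 0.0111) /min, scaled by the 0.1 mmol/kg dose. Signal is
converted to a concentration proxy by relative enhancement
$(S - S_0)/S_0$; no T1 mapping is attempted, so absolute parameter
values are interpretable only within the pipeline.

Numerics: the forward curve is evaluated by trapezoidal quadrature on
a 0.005-min internal grid via the exponential recursion (O(n), exact
for the trapezoid rule); it matches an independent ODE solver to
better than 0.1%. Fitting exploits linearity in $K^{trans}$: for
fixed $k_{ep}$ the optimal $K^{trans}$ is a closed-form projection,
so the nonlinear least-squares problem reduces to a 1D profile over
$k_{ep} \in [0, 5]$/min solved by a 51-point multi-start grid plus
local refinement. Fits are constrained to the physical region
$v_e \le 1$ (violating fits are re-solved on the $v_e = 1$ boundary
and flagged); all-zero curves return (0, 0, 0) with a `"flat"` flag.
Voxel-wise maps share one precomputed 501-point $k_{ep}$ basis across
all voxels, reducing a whole-region fit to a few matrix products.

# Feature table

The initial phase is the first postcontrast acquisition; the peak
phase maximizes mean intratumoral signal. Exactly two phases are
used because the feature arithmetic forces it:
99 × 5 × 2 regions × 2 phases = 1980. Voxel values of each map are
pooled across slices within each region (not averaged per slice — a
documented choice) and summarized by mean, median, SD (n−1),
moment skewness and non-excess kurtosis (Gaussian → 3); constant
regions report 0 for both standardized moments and are flagged. The
15 PK features are the same five statistics of the three parameter
maps over tumor ∪ ring.

Normalization maps each column affinely so the *reference* min/max
land on −1/+1, with out-of-range values clipped and constant columns
sent to 0. The reference is always the training cohort; holdout
tables are scaled by frozen training parameters so no test statistic
can leak into the model path.

# Feature discovery

Each mRMR run greedily selects 10 features by the MID criterion
(mutual information with the label minus mean mutual information with
the already-selected set), with MI estimated on 10-bin quantile
discretizations; ties break toward the lower column index. The
protocol then:

1. runs mRMR on every fold-training set of 200 iterations × 3
   stratified folds, counts selection frequencies pooled over all 600
   runs, and keeps the top ⌈10%⌉ (198 of 1980) — the "bottom 90%
   eliminated" reading;
2. repeats the same cross-validated selection inside the retained
   set, ranks by frequency again, greedily drops features correlated
   at |r| ≥ 0.9 with a higher-ranked survivor, and truncates to 10.

Frequency ties are broken by mean selection-time criterion score,
then lexicographic feature name, making the protocol fully
deterministic under a seed. For heavily imbalanced groups the
majority class can be downsampled (to 20 by default for the
HR+HER2− analysis) independently in every iteration. Folds are
always stratified — with only 10 minority patients, unstratified
folds would regularly lose a class.

# Consensus clustering

1000 iterations draw ⌊0.8 n⌋ patients without replacement, cluster
them hierarchically (average linkage, distance 1 − Pearson
correlation between patient feature vectors) and cut at k = 2. The
consensus of a pair is its co-clustering count divided by its
co-sampling count (0/0 → 0: never co-sampled pairs carry no
evidence); the final assignment clusters 1 − consensus with the same
linkage. Constant patient vectors have undefined correlations and
are placed at maximal distance with a warning. Per-class accuracy
maps each cluster to its majority label, which makes the readout
invariant to cluster id permutations. Clustering operates on
normalized features, consistent with the rest of the pipeline.

# Classifiers and evaluation

LDA and QDA come from MASS, Gaussian naive Bayes and the linear SVM
(C = 1, signed-margin scores) from e1071; DLDA — linear discriminant
with pooled *diagonal* covariance — is implemented directly, with
the n − 2 pooled-variance denominator so that it coincides exactly
with LDA whenever the pooled covariance happens to be diagonal.
Priors are empirical. Singular covariances (e.g. QDA with 10
features and 6 or 7 minority samples per fold) fall back to a
ridge-regularized Gaussian discriminant with a warning rather than
failing the fold.

AUC is the Mann–Whitney rank statistic with half credit for ties —
invariant under monotone score transforms. Accuracy, sensitivity
(pCR = positive class, fixed regardless of label encoding) and
specificity threshold posteriors at 0.5 and SVM margins at 0; an
optimized operating point was deliberately not used. Cross-validation
pools out-of-fold scores within each of the 50 repetitions, computes
metrics once per repetition, and reports mean ± SD across
repetitions. Sequential evaluation re-runs everything for the top-1
through top-10 feature prefixes.

# The phantom generator

Each phantom is a lobulated ellipsoid (nominal radius 6 mm,
15% boundary lobulation) on a 7 × 40 × 40 grid at 0.8 mm in-plane
spacing and 3 mm slices, imaged at the six standard phases with
baseline signal 100 and additive Gaussian noise (SD 0.5). Tumor
voxels follow the Tofts forward curve with class kinetics — pCR:
$K^{trans} = 0.25$, $k_{ep} = 0.6$/min; non-pCR: 0.4 and 0.9/min —
values in the range reported for breast lesions, with non-responders
enhancing more aggressively. Three class-linked texture effects are
planted:

* *peritumoral speckle* — multiplicative high-frequency noise on the
  ring enhancement (pCR 0.08, non-pCR 0.35), the "speckled
  enhancement" phenotype that Laws spot/ripple and Haralick features
  detect;
* *gradient disorder* — the tumor enhancement modulation
  interpolates between an ordered radial ramp and a smoothed random
  field (pCR 0.15, non-pCR 0.65), the contrast that CoLlAGe entropy
  measures;
* *enhancement heterogeneity* — the amplitude of that modulation
  (pCR 0.10, non-pCR 0.35).

Random fields are drawn in a fixed order so that phantoms with the
same seed but different effect amplitudes share identical underlying
noise — this makes ring-texture monotonicity in the amplitudes an
exact, testable property rather than a statistical one. The ring is
kept free of the gradient modulation for the same reason.

No quantitative description of real class texture differences was
available to calibrate against, so effect sizes are free parameters
chosen to be unambiguous: the resulting synthetic classes differ in
both kinetics and texture, and classifiers reach near-perfect AUCs on
them. Passing tests therefore demonstrate that the pipeline
*recovers planted structure faithfully* — not that any particular
AUC is attainable on clinical data. The phantoms also omit breast
anatomy, fat saturation artifacts, scanner and field-strength
effects, and motion.

# Problem sizes and determinism

The test suite and the acceptance script choose sizes that keep runs
reproducible on a single CPU: phantom pipelines at full study scale
(78 + 39 all-comers, 70 and 47 in the receptor groups) with the full
200-iteration discovery and 1000-iteration consensus; planted-recovery
studies at 120 samples × 505 features with a reduced 20-iteration
discovery (the protocol's behavior is iteration-count-stable well
below 200); unit tests on 16×16 slices and tiny 5 × 28 × 28 phantoms.
Every stochastic stage takes an explicit seed and is bit-reproducible;
generators restore the caller's RNG state.

# Known limitations

* The peritumoral ring ignores anatomy (no skin/chest-wall clipping).
* Relative enhancement is a proxy, not a concentration; absolute PK
  values are not comparable across protocols.
* Discovery and evaluation share the patient pool in the
  receptor-group experiment (as in the underlying design); the
  bundle records that the resulting CV estimates are optimistic.
* The mRMR mutual-information estimator uses fixed 10-bin quantile
  discretization; very small fold-training sets (< 30 samples) make
  the MI estimates noisy.
* Consensus clustering fixes k = 2; no model selection over k is
  attempted.
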