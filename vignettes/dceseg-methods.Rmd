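---
title: "Methods: temporal-feature supervoxel segmentation of DCE micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-feature supervoxel segmentation of DCE micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical decisions
behind `dceseg`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and where the design was genuinely open.

## The measurement model

A dynamic contrast-enhanced (DCE) acquisition yields volumes
$V_0, \dots, V_{T-1}$ on one grid, the first one pre-contrast. For a voxel
inside a tissue with pre-contrast intensity $T_0$, the post-contrast
intensity at time $t$ is modeled as

$$ T_t = T_0\,(1 + R_t), \qquad R_t = \frac{T_t - T_0}{T_0}, $$

where $R_t$ is the *relative enhancement*. The pipeline never needs
absolute calibration (no Hounsfield conversion): everything downstream
works on the *shape* of the enhancement curve, which differs between
organs because of perfusion and clearance. The working assumptions are
(i) a common grid across time points — the package applies no motion
correction, so breathing/cardiac displacement enters as label noise at
organ boundaries — and (ii) tissues that are homogeneous enough that a
supervoxel-level mean curve is representative.

## Stage by stage

### Temporal PCA (`build_time_matrix`, `fit_pca`, `score_volumes`)

The $V \times T$ matrix of voxel time curves is column-centered
(per-time-point means; "variance explained" is only meaningful after
centering — the convention followed here) and decomposed by SVD. The
first $n$ components are kept and each score column is min–max normalized
to $[0,1]$.

* `n_components = 4`: with six time points, ten tissue archetypes and
  additive noise, four components capture $>99\%$ of variance; the
  remaining components are noise-dominated. `score_volumes(basis, n =
  NULL, cum_var = 0.99)` supports a cumulative-variance rule for series
  with a different number of time points.
* Sign rule: a principal component's sign is arbitrary, so each
  component is flipped to make its largest-magnitude coefficient
  positive. This makes the whole pipeline deterministic.
* Degenerate input (no temporal variance) yields all-zero explained
  ratios with a warning rather than an error; a constant score column
  normalizes to all zeros with a warning.
* Normalization happens *after* component selection; since min–max
  normalization is invariant to the positive affine maps a different
  ordering would introduce, the choice is immaterial to the output.

### Supervoxels (`slic_supervoxels`)

A localized k-means over joint (feature, position) space with the
additive distance

$$ D = \frac{\sqrt{\tfrac1n \sum_k (b_{jk} - b_{ik})^2}}{m}
     + \frac{\sqrt{\sum_k (x_{jk} - x_{ik})^2}}{S}. $$

The two terms are normalized by the compactness $m$ (the feature scale
regarded as "comparable to one seed spacing") and the seed interval $S$,
then *added*. The classical SLIC combines the same two terms in
quadrature; both readings are implemented (`slic_distance(...,
combine = "quadrature")`), the additive form is the default. In practice
the two give nearly identical partitions away from boundaries; the
additive form penalizes simultaneous feature and spatial distance
slightly more.

* `S = 8` voxels: supervoxels of roughly $8^3$ voxels — small enough to
  resolve thin structures (renal pelvis, vessel walls) at the default
  grid, large enough to average noise.
* `m = 0.02`: with features in $[0,1]$, a feature RMS difference of 0.02
  "costs" as much as one seed spacing, i.e. boundaries follow features
  strongly. Decreasing $m$ tightens feature homogeneity **on clean
  data**; under voxel noise a very small $m$ chases noise, fragments
  clusters, and the connectivity merge can then *increase*
  within-supervoxel variance — the monotonicity property is only
  guaranteed, and only tested, on noise-free fixtures.
* Seeding: regular $S$-lattice (offset $\lfloor S/2\rfloor$), each seed
  moved to the minimum of the squared-central-difference gradient (summed
  over channels and axes) in its $3^3$ neighborhood; ties keep the
  lattice position. No randomness anywhere: the algorithm is exactly
  reproducible.
* Iterations: at most 10, stopping early when no assignment changes
  (always reached on the fixtures used here). Each center only competes
  for voxels in its $(2S+1)^3$ window; the lattice guarantees every voxel
  is covered.
* Connectivity: every label is split into 26-connected components; a
  label's largest component keeps it, fragments of at least `min_size =
  ceiling(S^3/4)` voxels become supervoxels of their own, smaller ones
  are absorbed by their largest 26-adjacent neighbor. A fragment may
  occasionally be absorbed diagonally across a feature boundary; this
  affects well below 1% of voxels on the fixtures and is accepted.

### Classification (`build_training_set`, `train_svm`, `train_rf`)

Supervoxels are classified into ten categories — heart, liver, spleen,
lung, kidney, bone, intestinal wall, intestinal cavity, subcutaneous
fat/muscle, and skin-adherent regions — from their mean feature vectors.
The four context classes exist so the classifier has somewhere to put
tissue the extractor does not produce.

* Training pools: a supervoxel is eligible for category $c$ if at least
  `purity = 0.8` of its voxels carry ground-truth label $c$ (purity
  $>0.5$ makes eligibility unique). By default the pipeline pools *all*
  eligible supervoxels and trains on a seeded 50% per-category subsample
  (`training_fraction`); `reference_category_counts()` provides a
  realistically sized per-category cap (451 supervoxels in total) for
  experiments on the influence of training-set size.
* SVM: RBF kernel via LIBSVM (package e1071), one-vs-one multiclass (the
  library's scheme). Cost $C = 2^{-5} \dots 2^{15}$ (21 values) and
  kernel shape $\gamma = 2^{-15} \dots 2^{15}$ (31 values), all 651 pairs
  scored by the pooled misclassification fraction of a stratified 5-fold
  cross-validation whose fold assignment depends only on the seed and
  the supervoxel ids (hence is invariant to row order). Ties prefer
  smaller $C$, then smaller $\gamma$ — the smoother model. Features are
  already in $[0,1]$, so no rescaling is applied.
* SVM probabilities: the default derives them from the decision function
  by pairwise coupling of sigmoid-mapped decision values with a *fixed*
  slope ($p_i \propto 1/(\sum_{j \ne i} 1/r_{ij} - (k-2))$, $r_{ij} =
  \text{logistic}(a\,d_{ij})$, $a = 4$ so that a unit functional margin
  maps to $\approx 0.98$ confidence). The conventional alternative,
  per-pair Platt calibration (`probability = "platt"`), is available but
  has a documented failure mode here: calibrated confidence grows with
  per-category training-set size, so with strongly unbalanced pools the
  small organs get systematically softer maps, and the Gaussian
  smoothing then erodes them in favour of the large context classes. A
  fixed-slope coupling keeps confidence independent of class size —
  mirroring the random forest, whose probabilities are plain vote
  fractions.
* Random forest: 500 trees, 2 candidate features per node (package
  randomForest); probabilities are the fraction of tree votes, hence
  multiples of 1/500. Degenerate single-category training sets yield a
  constant classifier (probability 1) rather than an error.

### Extraction and integration

* Probabilities are broadcast supervoxel-to-voxel and smoothed with a
  normalized, truncated, sampled $9^3$ Gaussian, $\sigma = 3$ voxels
  (about one supervoxel radius), applied separably with mirror
  reflection at the faces. One shared kernel keeps per-voxel sums at 1.
* Argmax labeling breaks exact ties toward the earliest category in the
  map's column order.
* Body mask: classification categories are only meaningful inside the
  animal, so the label volume is restricted to a body mask before
  extraction — Otsu air/tissue threshold on the pre-contrast volume,
  largest 26-connected component, cavities filled (this recovers the
  air-filled lung). Without it, surrounding air — which belongs to no
  category — would be forced into whichever class is nearest in feature
  space.
* Organ post-processing: binarize, open with a radius-2 *disk* applied
  per axial slice (the literal reading of a disk-shaped element in a
  slice-oriented workflow; a 3D ball is available via `element =
  "ball"`), select components, fill holes. Component selection keeps the
  largest component *and* every component at least half its size
  (`keep_ratio = 0.5`): mice have two kidneys and two lungs, and a
  largest-only rule would silently drop one. Connected components use
  26-connectivity (the 3D analog of the 2D 8-neighborhood;
  6-connectivity via argument). Hole filling is 3D: background not
  6-connected to the volume boundary.
* Bone: the pre-contrast histogram is thresholded in two stages — Otsu
  (air vs tissue), then Otsu above the soft-tissue mode (soft vs bone).
  When a histogram gap leaves a run of bins tied for the Otsu criterion,
  the middle of the tied run is used; taking the first tied bin would
  place the threshold at the soft-tissue edge and let noise leak in. On
  the post-contrast reference volume (the scan closest to 100 s, the
  time at which soft-tissue contrast is most informative), thresholding
  is restricted to the pre-contrast bone dilated by a radius-3 ball,
  which tolerates small rigid displacements while excluding strongly
  enhancing organs; a single reference volume is used rather than a
  union over time points. The dilation radius is a config parameter
  (`bone_dilation_radius`); 3 voxels accommodates the jitter amplitudes
  the phantom generates.
* Integration: masks merge under the priority bone > kidney > lung >
  liver > heart > spleen (most reliable structure first); contested
  voxels go to the highest-priority claimant.

### Evaluation

DSC, FPR and FNR are computed on voxel counts without spacing weights
(the grids here are isotropic). FPR and FNR are deliberately *not*
symmetric: both are normalized by the reference size. Paired runs are
compared with the two-sided Wilcoxon rank-sum test (`stats::wilcox.test`,
exact for small tie-free samples).

## The synthetic phantom

`default_phantom_spec()` encodes the study conditions: a
$100 \times 100 \times 180$ grid (0.315 mm voxels), six time points (one
pre-contrast, five post-contrast at 50 s intervals), all ten categories,
additive zero-mean Gaussian noise with SD 20 — 5% of the nominal
soft-tissue base intensity of 400 — and optional per-time-point integer
rigid jitter (default off, as no motion correction is applied).

Enhancement curves are explicit per-time-point tables rather than fitted
pharmacokinetic forms: published curves for this setting are only plotted,
never tabulated, so tables keep the ground truth exact. The defaults were
chosen once to satisfy the qualitative orderings the modality exhibits —
heart peaking at the first post-contrast scan (R: 1.6 → 0.4), kidney
sustained (1.2 → 1.55 → 1.4, last value above half the peak), spleen
washing out faster (1.1 → 0.3) than liver (0.9 → 0.65), muscle and
intestinal content below 0.05 throughout, bone (base 1400) strictly above
every enhanced soft tissue. Amplitudes are qualitative stand-ins, not
calibrated values.

What the phantom does *not* model: partial-volume ramps at boundaries,
beam hardening, scatter, reconstruction artifacts, anatomically realistic
shapes, or nonrigid respiratory/cardiac deformation. Passing the phantom
tests therefore demonstrates the pipeline's correctness and its noise
robustness, not its accuracy on real animals; on real data the soft
boundaries and motion will cost additional accuracy, most visibly for
small organs like the spleen.

## Problem sizes and determinism

The test-suite checks run the full pipeline on the default
$100\times100\times180$ phantom (about 3200 supervoxels, 651-pair SVM
search on roughly 900 training supervoxels) and verify: per-organ DSC
bars (0.85 for heart, liver, lung, kidney; 0.70 for the smaller, harder
spleen) for both classifiers; bit-for-bit reproducibility of a repeated
run; and stability (DSC range $<0.05$ for kidney and lung over five
seeded repetitions) when training on 30%, 50% and 70% of the pool —
run with the random forest, which keeps fifteen retrain cycles cheap;
the SVM is exercised at the 50% point by the recovery check. Unit tests
use smaller grids ($\le 64^3$) and brute-force oracles (set arithmetic,
BFS connected components, direct kernel evaluation, `prcomp`).

All randomness (noise, sampling, fold assignment, bagging, Platt's inner
CV) flows from explicit integer seeds through R's RNG; given one seed,
every stage — including LIBSVM probability calibration — is bit-for-bit
reproducible.

## Known limitations

* No motion correction; jittered series degrade boundary accuracy.
* The ten-category scheme is fixed; intestine and fat/muscle are
  context classes only and are not extracted as final organs.
* Eligibility-based training-pool construction approximates, but does
  not reproduce, expert selection of supervoxels "from different parts"
  of heterogeneous organs (no stratification by sub-region).
* Compactness monotonicity holds only in the low-noise regime (above).
* Voxel-count metrics assume isotropic spacing; no surface-distance
  metrics (Hausdorff, ASSD) are provided.
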