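# dceseg — organ segmentation of dynamic contrast-enhanced micro-CT mouse images

Soft-tissue organs are nearly invisible in native mouse micro-CT: at the
low doses tolerable for small animals, heart, liver, spleen and kidney all
sit in the same narrow intensity band. After a bolus of a non-ionic
iodinated contrast agent (iohexol), however, each organ traces a
characteristic intensity-versus-time curve — the cardiac blood pool
enhances immediately and washes out, the kidneys retain contrast through
renal clearance, the spleen washes out faster than the liver, and muscle
and intestinal content barely enhance. `dceseg` turns those temporal
signatures into a whole-body segmentation of the heart, liver, spleen,
lung, kidney and bone.

The package is aimed at preclinical imaging groups who have (or can
simulate) a short dynamic CT series — one pre-contrast scan plus a handful
of post-contrast scans — and want reproducible organ masks without an
anatomical atlas.

## Method

Given volumes at times `t = 0 … T−1` on a common grid:

1. **Temporal features.** The series is reshaped into a matrix **I**(X, t)
   whose rows are per-voxel time curves. A principal component analysis
   keeps the first *n* = 4 temporal components (> 99 % of the variance);
   each voxel's component scores, min–max normalized to [0, 1], become its
   feature vector *b* = (b₁ … bₙ).
2. **Supervoxels.** An n-feature 3D SLIC clusters voxels under the
   additive distance

   D = √( (1/n) Σₖ (b_jk − b_ik)² ) / m + √( Σₖ (x_jk − x_ik)² ) / S

   with seed interval `S = 8` voxels and compactness `m = 0.02`. Centers
   start on a regular S-lattice, move to the lowest-gradient position in a
   3×3×3 neighborhood, and iterate a windowed (2S)³ k-means; connectivity
   is then enforced.
3. **Classification.** Each supervoxel's mean feature vector is classified
   into ten tissue categories by an RBF-kernel SVM (cost and kernel shape
   selected over the 21 × 31 grid 2⁻⁵…2¹⁵ × 2⁻¹⁵…2¹⁵ by stratified 5-fold
   cross-validation) or a random forest (500 trees, 2 candidate features
   per split). Both emit per-category probabilities.
4. **Extraction.** Probabilities are broadcast to voxels, smoothed with a
   9×9×9 Gaussian (σ = 3), and converted to labels by per-voxel argmax
   inside a body mask. Each organ mask is cleaned by a radius-2 disk
   opening, connected-component selection and hole filling. Bone is
   segmented by histogram thresholding of the pre-contrast scan,
   constrained on the post-contrast reference scan to a dilated bone ROI.
5. **Integration.** Masks are merged under the priority
   bone > kidney > lung > liver > heart > spleen.
6. **Evaluation.** Against a reference Y, a segmentation X is scored by
   DSC = 2|X∩Y|/(|X|+|Y|), FPR = |X\\Y|/|Y| and FNR = |Y\\X|/|Y|; runs are
   compared with the two-sided Wilcoxon rank-sum test.

Because no public DCE micro-CT dataset with labels exists, the package
ships a synthetic 4D phantom generator (`default_phantom_spec()`,
`phantom_generate()`) producing a mouse-like ten-tissue volume with known
enhancement curves, ground-truth labels, Gaussian noise and optional rigid
jitter — every stage of the pipeline is testable offline.

## Worked example

```r
library(dceseg)

spec <- default_phantom_spec(seed = 7)          # 100 x 100 x 180, noise SD 20
ph   <- phantom_generate(spec)
print(ph$series)
#> DCE series: 6 time points, 100 x 100 x 180 grid, 0.315 mm voxels
#>   times (s):-50, 0, 50, 100, 150, 200 [pre-contrast index 1]

feats <- dce_features(ph$series, n_components = 4)
print(feats$basis)
#> Temporal PCA basis: 6 components
#>   explained variance: 0.9834 0.0101 0.0029 0.0013 0.0012 0.0012

cfg <- pipeline_config(classifier = "rf", seed = 8)
seg <- dce_segment(ph$series, cfg, truth = ph$labels)
report <- evaluate_segmentation(seg$result, ph$labels, comparison_id = "RM1")
print(report, digits = 3)
#>    organ   DSC      FPR    FNR n_seg n_ref comparison
#> 1 kidney 0.905 0.000000 0.1742  7226  8750        RM1
#> 2   lung 0.934 0.000394 0.1237 13345 15222        RM1
#> 3  liver 0.985 0.003731 0.0265 36408 37255        RM1
#> 4  heart 0.900 0.000000 0.1813  4150  5069        RM1
#> 5 spleen 0.934 0.003145 0.1204  4771  5405        RM1
#> 6   bone 1.000 0.000000 0.0000 13041 13041        RM1
```

The first four temporal components capture > 99 % of the variance; every
organ is recovered with DSC ≥ 0.90 against the phantom ground truth (DSC
1 = perfect overlap; FPR/FNR are the spurious and missed voxel fractions
relative to the truth). Region kinetics can be read back with
`relative_enhancement()` — for the kidney of this phantom it returns its
generating curve `R_t = (1.20, 1.50, 1.55, 1.50, 1.40)` up to noise.

A command-line interface wrapping the same functions is installed at
`inst/cli/dceseg.R` with subcommands `phantom`, `features`, `supervoxels`,
`train`, `segment` and `evaluate` (see `dceseg_cli()`).

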