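---
title: "Quantifying intratumoral heterogeneity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral heterogeneity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadHet)
```

## The problem

Invasive lung adenocarcinoma is rarely a single growth pattern: most
resected tumors mix two or more of the five IASLC/ATS/ERS patterns
(lepidic, acinar, papillary, micropapillary, solid), and the mixture — not
just the predominant pattern — carries prognostic information. Pathology
quantifies the mixture from the resected specimen; imaging sees the whole
tumor before resection. RadHet implements the quantitative bridge between
the two: a 51-feature radiomic description of a 3D CT tumor region (on the
virtual non-contrast and iodine-map channels of dual-energy CT), a
pathologic heterogeneity index summarizing the subtype mixture, and the
statistics connecting them.

## The feature battery

All features are computed strictly inside the ROI mask; voxels outside the
mask never enter any computation, and degenerate values (a single-voxel
ROI, zero variance) are reported as missing rather than zero-filled.

**Physical (4).** Volume (voxel count times voxel volume, cm^3); density
via the CT mass convention $\rho = (\mathrm{HU} + 1000)/1000$ g/mL, floored
at 0 per voxel; mass = volume x density; size as the maximal in-plane
(axial) diameter in mm, the clinical tumor-size convention (a 3D maximum
diameter is available via `size3d = TRUE`). The density convention is the
only reading under which a ground-glass tumor lands near 0.6 g/mL and an
iodine-map ROI near 1.2 g/mL, consistent with how such values are reported
in the clinical literature.

**Histogram (7).** Skewness $m_3/m_2^{3/2}$ and non-excess kurtosis
$m_4/m_2^2$ with $1/N$ central moments (a normal distribution scores 3),
plus the 2.5th/25th/50th/75th/97.5th HU percentiles by linear interpolation
between order statistics (R's type-7 quantile).

**Regional (4).** Uniformity $\sum h^2$ and entropy $-\sum h \log_2 h$ of a
fine histogram profile (256 equal-width bins over a fixed window), and the
two size-zone non-uniformities computed from the gray-level size-zone
matrix: zones are maximal 26-connected components of equal quantized level
(6-connectivity is available), and
$\mathrm{IV} = \sum_g (\sum_s z_{gs})^2 / N_z$,
$\mathrm{SZV} = \sum_s (\sum_g z_{gs})^2 / N_z$. Implementing
uniformity/entropy as histogram statistics (rather than zone-matrix
statistics) keeps their scale in the 7–9.5-bit regime expected of
fine-binned CT histograms and keeps them distinct from the much coarser
local entropy.

**Local (36).** Twelve co-occurrence statistics at voxel distances 1, 2, 3:
energy, entropy, correlation, contrast, variance, sum mean, inertia,
cluster shade, cluster tendency, homogeneity, maximum probability, inverse
variance. The co-occurrence matrix for an offset is the symmetrized,
normalized count of ordered foreground voxel pairs separated by exactly
that offset; features are computed per direction over the 13 canonical 3D
directions and averaged (feature averaging, not matrix averaging — the
common radiomics convention), skipping directions that contribute no valid
pair. Offsets are in voxel units; anisotropic spacing intentionally does
not rescale them. Contrast is implemented as the first-order difference
moment $\sum |i-j| p_{ij}$ and inertia as the second-order moment
$\sum (i-j)^2 p_{ij}$, so the two report different aspects of local
gradient structure instead of duplicating one another. Entropy is in bits
throughout. When a single gray level is occupied the marginal SD is zero
and correlation is reported missing; every other feature stays defined.

## Quantization: two profiles, fixed HU windows

CT intensities are already calibrated (HU), which argues for fixed-bound
discretization rather than per-ROI range adaptation:

* **texture profile** — 16 equal-width levels over [-1000, 400] HU, feeding
  the co-occurrence and size-zone matrices;
* **histogram profile** — 256 equal-width bins over the same window, behind
  regional uniformity/entropy.

Binning over each ROI's observed range (available via `huRange = NULL`) has
a subtle failure mode for heterogeneity work: a tumor spanning a wide HU
range gets proportionally wider bins, so adjacent same-tissue voxels
co-quantize more often and homogeneity *rises* — and local entropy can fall
— exactly for the most mixed tumors. Fixed windows keep the bin width
constant across the cohort, so a tumor composed of several HU populations
genuinely occupies more levels than a uniform one. The topmost bin is
right-closed; values outside the window clip into the extreme bins;
quantization is monotone and invariant to joint shifts of values and
window.

## The pathologic heterogeneity index

Comprehensive subtyping reports each growth pattern to the nearest 5%,
summing to 100% (central fibrosis is recorded separately and excluded from
the simplex). Raw tables are repaired deterministically: renormalize to
100, allocate the twenty 5%-units by largest remainder (ties: larger raw
share, then the fixed aggressiveness order solid > micropapillary >
papillary > acinar > lepidic, which also breaks predominance ties).

The index is the hazard-weighted mixture score
$$\mathrm{HI} = \sum_s w_s \, p_s / 100,$$
linear in the proportions. The shipped weights (lepidic 0, acinar 1,
papillary 1, micropapillary 2, solid 2) are package defaults ordered by the
established prognostic gradient of the subtypes; they are configuration,
not estimates, and any published disease-free-survival hazard-ratio set can
be substituted wherever a `weights` argument appears. Tumors are also
grouped by the number of strictly positive subtypes: ONE, TWO, or
THREE_OR_FOUR, the grouping used by the ANOVA stage.

## The statistical battery

* **Spearman** correlation of each feature with the index, with strength
  bands on $|\rho|$: [0, 0.2) very weak, [0.2, 0.4) weak, [0.4, 0.6)
  moderate, [0.6, 0.8) strong, [0.8, 1] very strong. For $n \le 9$ the
  p-value is the exhaustive two-sided permutation tail over all $n!$ rank
  permutations; beyond that the usual $t$ approximation on $n-2$ degrees of
  freedom. No multiplicity correction is applied; reports carry raw
  p-values and say so.
* **ANOVA + Tukey HSD** across the three subtype-count groups, with the
  Tukey–Kramer unequal-$n$ correction; identical data across groups
  degenerate to $F = 0$, $p = 1$ instead of erroring.
* **Lin's concordance** $\mathrm{CCC} = 2 s_{xy} / (s_x^2 + s_y^2 +
  (\bar x - \bar y)^2)$ with population ($1/n$) moments, for dual-reader
  feature stability; per-feature values are classified reproducible at the
  conventional 0.85 threshold. Two identical constant readings score 1; any
  other zero-variance pairing scores 0.
* **Model validation**: bidirectional stepwise selection by AIC from the
  intercept-only Gaussian linear model, then ten-fold cross-validation with
  the entire selection re-run inside each training fold, reporting the
  Pearson correlation of out-of-fold predictions with the index alongside
  the (optimistic) in-fold value. Because performance is judged by a
  correlation with a continuous index, the Gaussian model is the primary
  path; a logistic variant on the median-split index is available via
  `family = "binomial"`. Fold assignment is seeded and mandatory — every
  report embeds its seed and configuration, and identical configuration
  reproduces every output byte for byte.

A caveat worth knowing: cross-validated correlation is *negatively* biased
under a null target when models collapse toward the intercept, because
fold-training means anti-correlate with their held-out folds (medians near
-0.2 to -0.3 in simulation). With candidate sets as large as this
pipeline's (51 features), spuriously selected features add
prediction variance that dilutes the artifact and the null median returns
to about zero. Null simulations should therefore match the pipeline's
candidate dimension, as the test suite does.

## The phantom generator

`makePhantom()` builds an ellipsoidal tumor on a voxel grid, partitions it
into spatial compartments matching a ground-truth subtype composition
(seeded interior points with quota-constrained nearest-seed assignment:
contiguous, irregular territories whose realized volume fractions match the
composition to within 5 percentage points by construction), draws each
compartment's voxels from its subtype's HU distribution, and adds global
Gaussian noise (default SD 20 HU, a typical soft-kernel reconstruction
noise level). Default emission parameters follow the radiologic
ground-glass-to-solid spectrum — lepidic N(-650, 80), acinar N(-300, 90),
papillary N(-150, 90), micropapillary N(-50, 80), solid N(30, 60) on the
non-contrast channel, with an iodine-map analogue ordered by expected
vascularity. These are invented, documented defaults: only their ordering,
never their absolute values, is relied on by any test.

`makeCohort()` draws mixture sizes from the 21/61/16/2% distribution
observed in a published 89-tumor resected cohort, weights subtype
combinations toward the combinations frequent in that cohort, sizes tumors
at ellipsoid radii of 7–12 voxels at 1 mm spacing (1–4 cm tumors), and
emits NIfTI volumes, masks, a pathology CSV and a JSON manifest with seeds
and ground truth. Problem sizes used by the shipped tests and acceptance
script — 150-tumor cohorts for the end-to-end checks, 25 tumor pairs for
the stability study, 100-seed simulations for the statistical calibration —
were chosen as the package's standard demonstration scale.

**What the phantoms do and do not emulate.** They emulate compartmental HU
mixtures, additive noise, 5%-grid compositions, and cohort-level mixture
frequencies. They do not emulate CT physics (beam hardening, kernels,
partial-volume blur), lesion-background texture continuity (the background
is uniform air), within-subtype biological texture, or spatial correlation
of noise. Two consequences matter for interpreting green tests. First,
because a phantom sits in exact air, an *outward* mask perturbation ingests
background rather than plausibly re-delineating tissue, so the dual-reader
stability study perturbs masks *inward* (1-voxel erosion: both readers stay
on tumor tissue); morphology-driven features (volume, size) still shift
systematically, which is also what real dual-reader studies show. Second,
passing directionality checks on phantoms demonstrates that the pipeline
recovers planted compartmental structure — not that real tumors behave this
way.

## The identity–count confound

The end-to-end checks assert two distinct patterns, and the distinction is
deliberate. Across subtype-count groups (ONE / TWO / THREE_OR_FOUR), group
means of local and regional entropy escalate, homogeneity declines, and the
upper histogram percentiles rise: more compartments genuinely mean more
occupied gray levels and more level transitions. Against the *index*,
however, local entropy correlates weakly negatively and homogeneity weakly
positively on these cohorts, while density, the upper percentiles (positive)
and skewness (negative) carry the strong correlations. The index weights
*which* subtypes are present more than *how many*: a pure-acinar tumor
(index 1) is textureally uniform, while a lepidic-plus-acinar mixture with a
lower index has two-population texture. Texture features track compartment
count; the index tracks compartment identity — both axes are real and the
reports expose both, which is why the correlation table and the
group-comparison table are separate deliverables.

## Degenerate inputs and numerical conventions

* Empty masks and shape mismatches are errors at extraction; a constant ROI
  with an adaptive (`NULL`) range is a degeneracy error instructing the
  caller to pass a window.
* Single-voxel and pairless ROIs keep physical/histogram/regional features
  and report texture as missing; extraction over a cohort records per-row
  failures and continues, erroring only if every row failed.
* $0 \log 0 \equiv 0$ in every entropy; co-occurrence probabilities sum to
  1 within 1e-12 whenever pairs exist.
* ROI traversal is fixed column-major order; coordinates are 0-based; masks
  must already live on the image grid (no resampling stage is provided, by
  design — resampling is an acquisition-harmonization concern upstream of
  this package).
* Stepwise ties are resolved by candidate column order; fold assignment by
  one seeded shuffle.

## Limitations

Absolute feature values are convention-dependent (binning, aggregation,
normalization differ across radiomics implementations), so cross-package
comparisons should be made on directions and ranks, not raw magnitudes.
The index weights are configurable placeholders pending a cohort-derived
hazard set. The generator's compartment geometry is a coarse proxy for
growth-pattern architecture; survival analysis and DICOM/dual-energy
reconstruction are out of scope.
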