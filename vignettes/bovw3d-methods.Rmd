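---
title: "Methods: interpretable 3D bag-of-visual-words analysis of volumetric microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable 3D bag-of-visual-words analysis of volumetric microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Volumetric fluorescence microscopy often reveals condition differences that
an expert can see but cannot reduce to a single hand-crafted measurement:
chromatin reorganizes, receptors cluster, texture smooths or fragments, and
the signal lives in genuinely three-dimensional structure. `bovw3d`
implements a deliberately simple, fully inspectable pipeline for this
setting: local 3D structure is summarized by multiscale keypoint
descriptors, images become histograms of learned "visual words", a linear
classifier separates conditions, and — because the classifier is linear —
every decision can be decomposed back onto the voxels that produced it.
Each stage is ordinary, auditable arithmetic; nothing is a black box.

## Pipeline model

For a single-channel volume $V$ (axis order $z,y,x$, optional nuclear mask):

1. **Normalization.** Intensities are clipped to the 5th–95th percentiles
   (computed over in-mask voxels when a mask exists, so background does not
   set the scale) and affinely mapped to $[0,1]$.
2. **Keypoints.** A 3D difference-of-Gaussians (DoG) scale space is built
   at scales $\sigma \in \{1.0, 1.6, 2.2, 3.0\}$ voxels over three octaves
   (each octave halves the grid). With $D_i = G_{\sigma_{i+1}} * V -
   G_{\sigma_i} * V$, strict $3{\times}3{\times}3$ extrema with
   $|D| > t_c$ are keypoints: DoG minima mark bright blobs, maxima dark
   blobs. Octave coordinates map back by the octave's power of two. A 3D
   Hessian edge filter removes plate- and tube-like responses whose
   eigenvalue ratio $|\lambda_{\max}|/|\lambda_{\min}|$ exceeds $t_e$.
3. **Descriptors.** Around each keypoint a cubic patch of edge
   $\mathrm{odd}(5\,\sigma\,2^{\mathrm{octave}})$ is taken (rejected at
   volume borders, or when under half of it lies in the mask). Gradients
   come from finite differences of the normalized volume; each voxel's
   gradient is expressed in spherical angles $(\theta, \phi)$. Instead of
   absolute orientations, each voxel is compared with its 26 neighbors:
   the differences $(\Delta\theta, \Delta\phi)$ select one of
   $4 \times 8 = 32$ histogram bins, into which the magnitude ratio
   $m_q / (m_p + \varepsilon)$ is accumulated. Relative angles and ratios
   make the histogram approximately rotation invariant and exactly
   intensity-scale invariant; the descriptor is L2-normalized.
4. **Encoding.** A 200-word codebook is learned by sparse dictionary
   learning on descriptors pooled across the whole dataset; each
   descriptor is then soft-assigned: encoded as sparse coefficients over
   the entire dictionary.
5. **Image vectors.** Per image, absolute coefficients are summed into a
   200-dimensional word-usage vector, reweighted by smoothed inverse
   document frequency $\mathrm{idf}_k = \ln\frac{1+N}{1+\mathrm{df}_k}+1$,
   and L2-normalized (removing sensitivity to keypoint count). UMAP of
   these vectors is available for visualization only.
6. **Classification.** L2-regularized logistic regression (two-class
   AUC-ROC; four-class confusion matrix), evaluated by stratified 5-fold
   cross-validation with a fixed seed.
7. **Attention.** For an image vector $x$ and weight vector $w$, each word
   contributes $c_k = w_k x_k$ to the decision value; $c_k$ is
   redistributed over patches proportionally to each patch's absolute
   usage of word $k$. Patch scores sum exactly to $\sum_k w_k x_k$, and
   their volumetric rendering (uniform spreading over each patch cube)
   conserves that sum voxelwise.
8. **Quantification.** A single global threshold (90th percentile of
   positive rescaled attention, pooled over the dataset) defines
   high-attention voxels; 26-connected components give blob counts and
   volumes; high-attention patches are quantized (1st–99th percentile
   clip, 32 gray levels, background level 0) and summarized by 13 Haralick
   co-occurrence features at distance 1 with zeros ignored, averaged over
   the 13 unique 3D directions.

```{r}
library(bovw3d)
ds <- make_dataset(fixture_spec(seed = 1))
res <- run_pipeline(ds, config = pipeline_config(seed = 1))
res
```

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `norm_lo_pct`, `norm_hi_pct` | 5, 95 | robust intensity window per nucleus; percentiles over in-mask voxels so background never dominates |
| `sigmas` | 1.0, 1.6, 2.2, 3.0 voxels | detector scales; voxel units on all axes (anisotropy is not rescaled — the same detector is used on anisotropic stacks) |
| `n_octaves` | 3 | factor-8 scale coverage; octaves smaller than the 5-voxel stencil are skipped |
| `contrast_thresh` | 0.01 | minimum \|DoG\| on the [0,1] intensity scale; classic SIFT-lineage value |
| `edge_ratio_thresh` | 10 | Hessian anisotropy cut; 1 = perfectly isotropic blob |
| `min_mask_frac` | 0.5 | patch retained if at least half its voxels are in-mask; the threshold is a judgment call, exposed in config |
| `n_theta`, `n_phi` | 4, 8 | orientation-difference bins; 32-D descriptors stay compact relative to the 200-word codebook while resolving orientation structure |
| `K` | 200 | codebook size |
| `sparsity`, `dict_iter` | 5, 10 | OMP nonzero budget and coding/update alternations; unstated upstream, fixed here for reproducibility |
| `C` | 1.0 | inverse L2 regularization (`lambda = 1/(nC)`) |
| `threshold_pct` | 90 | global attention threshold as a percentile of positive rescaled attention — a reproducible stand-in for an "empirically chosen" constant |
| `connectivity` | 26 | blob connectivity (6 and 18 selectable) |
| `quant_levels` | 32 | gray levels for co-occurrence statistics |

## The synthetic stated world

Real chromatin and receptor-clustering datasets are not redistributable, so
the package carries a generator whose defaults define the reference world
used by every end-to-end test:

* **Nuclei mode** — 20 images per class on a $40^3$ grid; ellipsoidal
  masks with radius $13 \pm 1$ voxels and up to 12% per-axis jitter.
  Class A (control-like) has punctate texture: 25 Gaussian foci of
  $\sigma = 1.5$ voxels. Class B (perturbation-like) is smooth: 4 broad
  blobs of $\sigma = 5$, plus a 1.3-fold nuclear volume increase
  emulating loss-of-function nuclear enlargement. Both share a diffuse
  base level (0.15) and additive Gaussian noise ($\sigma = 0.05$,
  a realistic ~5% of peak signal).
* **Timelapse mode** — whole-field frames with five overlapping "cells"
  each, no masks, and 4-fold axial downsampling emulating coarse confocal
  z-sampling; four conditions crossing ligand response (diffuse → many
  compact puncta) with a polarity-protein overexpression (fewer, larger,
  brighter clusters).

The generator emulates the *statistical* structure that matters to the
method — blob scale and density contrasts, nuclear size shifts, masked
feature extraction, axial anisotropy — and deliberately not the optics: no
PSF, no photobleaching, no multi-channel correlation. A green end-to-end
test therefore establishes that the pipeline recovers texture-scale class
structure and its direction (the smooth class scores higher
inverse-difference-moment and lower contrast in high-attention regions);
it does not certify performance on any particular instrument's data.

## Numerical choices

* **DoG sign.** DoG = more-blurred − less-blurred, so bright blobs are
  minima; strict extrema only (plateaus in quantized data would otherwise
  fire), and border voxels are never extrema.
* **Blur boundaries.** Separable Gaussian kernels truncated at $4\sigma$
  with half-sample mirror boundaries; downsampling keeps every second
  voxel of the most-blurred level (classic cascade).
* **Angle wrapping.** $\Delta\theta = |\theta_p - \theta_q| \in [0,\pi]$
  (the polar difference is reflective); $\Delta\phi$ wraps periodically to
  $[-\pi,\pi)$. $\varepsilon = 10^{-8}$ floors the magnitude ratio, and
  voxels with $m_p < \varepsilon$ contribute nothing.
* **Relative magnitude.** The ratio $m_q/(m_p+\varepsilon)$ is used as the
  accumulation weight of a single orientation histogram rather than as a
  separate binning axis — the main descriptor design judgment, chosen to
  keep the descriptor compact; intensity-scale invariance survives either
  way.
* **Pooling sign.** Sparse-coding coefficients can be negative; usage
  pools absolute values so that word "frequencies", the idf presence
  counts, and the proportional attention redistribution are all
  well-defined (`pool_image(absolute = FALSE)` gives the signed
  alternative).
* **Conservation conventions.** The intercept is excluded from the
  attention decomposition (it has no spatial support); uniform
  within-patch spreading makes voxel sums conserve patch scores exactly,
  with Gaussian weighting as a display option.
* **Degenerate inputs.** Constant volumes normalize to zeros with a
  warning rather than an error (a batch must survive one degenerate
  crop); constant attention maps rescale to zeros; zero-variance Haralick
  patches set correlation and both information measures to 0; patches
  with no valid co-occurring pair are flagged invalid and excluded from
  pooling.
* **Haralick conventions.** Natural logarithms; sum variance is taken
  about the sum average; co-occurrence matrices are symmetrized and
  normalized per direction before feature computation, and directions
  with no valid pair are excluded from the average.
* **Determinism.** Every stochastic step (dictionary initialization and
  subsampling, fold assignment, UMAP) runs under an explicitly passed
  seed with caller RNG state restored; repeated runs are bit-identical.
* **Percentile idempotence.** Re-normalizing an already-normalized volume
  is a fixed point only up to clipping tolerance: clipping concentrates
  mass at the window edges, which shifts re-estimated percentiles by
  under 1%.

## Open design decisions taken

* **Per-condition median split.** Size stratification keeps perturbed
  images above *their condition's* median volume and control images below
  theirs — the literal reading of "larger perturbed, smaller control" —
  rather than one global median; the global variant is a trivial caller
  change.
* **Per-frame normalization.** Timelapse fields of view are normalized per
  frame (not per series); whether upstream practice differs is unknown,
  and per-frame is the choice that never leaks information across time.
* **Signed vs rescaled thresholding.** Blob analysis defaults to the
  min–max rescaled positive attention maps (threshold on `rescaled`, with
  the signed `render` available), since per-image rescaling is what makes
  one global threshold meaningful across nuclei of very different decision
  magnitudes.
* **Multiclass attention** uses the weight vector of the image's true
  class by default (any class selectable).
* **Evaluation protocol.** Published AUCs rarely state their splitting;
  the default here is stratified 5-fold cross-validation with a fixed
  seed, and `n_folds = 0` gives the in-sample fit for comparison.
* **High-attention patch geometry** reuses the keypoint patches whose
  centers fall in high-attention voxels, keeping descriptor, attention and
  texture provenance aligned voxel-for-voxel.

## Known limitations

* The method is intensity-keypoint driven: a channel with very homogeneous
  signal yields few keypoints and an uninformative representation — that
  is a property of the approach, not a bug.
* One channel at a time; joint multi-channel structure (colocalization) is
  out of scope.
* Scale space is isotropic in voxel units; strongly anisotropic spacing is
  handled by the descriptor's robustness, not corrected in the detector.
* Descriptor rotation invariance is approximate: exact under rotations
  about the polar axis, empirically ≥0.99 cosine similarity under the 24
  axis-aligned grid rotations and ≥0.95 under small resampled rotations of
  smooth patches (the test suite measures exactly this).
* No subvoxel keypoint refinement and no probability calibration.
* TIFF support is deliberately minimal (uncompressed, single-channel,
  striped, 8/16-bit integer or 32-bit float) — the package writes what it
  reads; compressed or tiled files from other software must be converted
  first.
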