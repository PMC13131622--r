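# bovw3d

Interpretable 3D bag-of-visual-words analysis of volumetric fluorescence
microscopy, for biologists and image analysts who need to (i) tell
experimental conditions apart from single-channel 3D images and (ii) see
*where in the volume* and *in what texture* the discriminative signal
lives — without neural networks and without collapsing stacks to 2D.

## Method

For each volume (optionally restricted to a nuclear mask):

1. **Normalize**: clip to the 5th–95th in-mask percentiles, rescale to [0, 1].
2. **Detect keypoints**: 3D difference-of-Gaussians scale space,
   σ ∈ {1.0, 1.6, 2.2, 3.0} voxels over three octaves; strict 3×3×3
   extrema above a contrast threshold (DoG minima = bright blobs), with a
   3D Hessian edge filter (|λ_max|/|λ_min| ≤ 10).
3. **Describe**: cubic patches of edge 5σ; each voxel's gradient is
   expressed *relative to its 26 neighbors* — orientation differences
   (Δθ, Δφ) binned 4×8, weighted by magnitude ratios — giving 32-D,
   rotation-robust, intensity-scale-invariant descriptors.
4. **Encode**: a 200-word codebook by sparse dictionary learning on the
   pooled descriptors; soft assignment of every patch over the whole
   dictionary.
5. **Image vectors**: per-word sums of |coefficients|, TF-IDF weighting
   idf_k = ln((1+N)/(1+df_k)) + 1, L2 normalization; UMAP for display.
6. **Classify**: L2-regularized logistic regression; stratified 5-fold CV
   AUC-ROC (two classes) or confusion matrix (four classes).
7. **Interpret**: word contributions w_k·x_k are redistributed to patches
   in proportion to absolute word usage — patch scores sum *exactly* to the
   linear decision value — and rendered as volumetric attention maps.
8. **Quantify**: one global attention threshold; 3D connected-component
   blob counts/volumes; 13 Haralick co-occurrence features (distance 1,
   32 gray levels, zeros ignored, averaged over 13 directions) of the
   high-attention patches.

Real microscopy inputs are multi-page TIFF stacks plus a CSV manifest; a
built-in generator produces masked synthetic nuclei (punctate vs smooth
texture) and anisotropic multi-cell "timelapse" fields so the entire
pipeline is testable offline.

## Worked example

```r
library(bovw3d)

ds  <- make_dataset(fixture_spec(seed = 1))   # 20 punctate + 20 smooth nuclei
res <- run_pipeline(ds, config = pipeline_config(embed_method = "none", seed = 1))
res
#> <bovw_pipeline_result>
#>   images: 40 (A=20, B=20)
#>   codebook: 200 words x 32 dims
#>   AUC-ROC (5-fold CV): 0.998
#>   attention threshold: 0.2928; mean blobs/image: 5.6

tex <- res$texture$per_image
tapply(tex$inverse_difference_moment, tex$condition, mean)
#>     A     B
#> 0.267 0.399
tapply(tex$contrast, tex$condition, mean)
#>    A    B
#> 53.8  7.2
```

The cross-validated AUC of 0.998 says the 200-word vectors separate the
two texture classes almost perfectly. The texture means point the right
way: the smooth class B has *higher* inverse difference moment (more
homogeneous) and *lower* contrast inside its high-attention regions than
the punctate class A — the pipeline not only classifies but recovers the
direction of the underlying texture difference. Per-image blob statistics
are in `res$blobs`, per-patch attention in `res$attention`, and
`embed_2d(res$vectors$normalized)` gives a 2D UMAP of the images.

A thin command-line wrapper (`inst/scripts/bovw3d-pipeline.R`) exposes
`simulate` and `run-all` subcommands over the same functions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic dataset from the given seed, runs the
complete pipeline (keypoints → descriptors → codebook → TF-IDF vectors →
cross-validated classifier → attention maps → blob and texture analysis),
logs the summary statistics, and writes the JSON results file.
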