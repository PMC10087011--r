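---
title: "Multimodally corroborated spatial segmentation of MSI data"
author: "kappaMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodally corroborated spatial segmentation of MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappaMSI)
```

## The problem and the model

Clustering the pixel spectra of a mass spectrometry imaging (MSI)
acquisition segments the tissue section into candidate regions of interest,
but the number of clusters K is chosen by the user, and internal validity
indices disagree with each other because they only ever see the MSI data —
noise included. This package treats a co-acquired H&E image of a serial
section as an *external* referee. The whole-slide image is cut into tiles
of exactly one MSI pixel's physical size and each tile is encoded as a
histomorphological feature (HF) spectrum, giving a second hyperspectral
cube on the same pixel grid whose channel axis is morphology rather than
m/z. Both cubes are segmented identically, and the agreement between the
two segmentations, as a function of K, becomes the model-selection
criterion.

Agreement is Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, computed on
the K-by-K contingency table of the two labelings over the pixels that are
foreground in both modalities: $p_o$ is the observed agreement and $p_e$
the chance agreement from the product of marginal proportions, so kappa is
not biased toward small K the way raw percent agreement is. Cluster ids
carry no meaning across modalities, so kappa is maximized over relabelings
of one side. Two details matter:

* the search must maximize kappa itself, not observed agreement — $p_e$
  depends on which marginals are paired, so the best-agreement permutation
  is not always the best-kappa permutation;
* the search is exhaustive for K ≤ 9 (at most 9! = 362,880 permutations,
  evaluated vectorized on the contingency table). For larger K a Hungarian
  assignment on the agreement counts initializes a pairwise-swap local
  search, with an explicit warning that it may be suboptimal.

Ties in the curve resolve to the smallest K (parsimony). The selected K\*
is where both modalities tell the same spatial story; clusters that only
one modality produces (noise, artefacts, or genuinely modality-specific
structure) depress kappa and are never selected.

## Pipeline stages and the parameters that matter

**MSI preprocessing.** TIC normalization rescales every foreground pixel to
the dataset's mean foreground TIC (units stay acquisition-like; zero-TIC
pixels are flagged, not rescaled). The peak pipeline runs a fixed stage
order — Savitzky–Golay smoothing (window 9), rolling-minimum baseline
reduction, local-maximum peak picking (SNR 3 over the residual noise
estimate, plus a 5 % relative-height floor that guards against
baseline-subtraction residue on clean profiles), greedy 1-D alignment of
pooled centroids (tolerance 0.05 Da, sensible for a resolving power around
10,000), binning to consensus centers (mean of contributing centroids), and
a 1 % pixel-frequency filter. No published parameter set exists for these
stages, so the defaults follow common MSI practice and every value is
exposed in `preprocess.*` config keys. Tissue masking thresholds the summed
intensity of tissue-specific ions (Otsu by default, manual cutoff
supported); if no ion list is given, a provisional TIC mask bootstraps one.
Ions whose background mean exceeds their foreground mean are dropped as
ambient.

**HF encoding.** The tile edge is `round(msi_pixel_um / he_pixel_um)` and
must sit within 1 % of the exact ratio; tiles with at least 90 % tissue
(inclusive) are foreground. Two extractor backends exist behind one
interface. The `densenet201` backend is a genuine from-scratch DenseNet-201
forward pass (im2col convolutions on BLAS; stem 7×7/2 + max-pool, dense
blocks 6/12/48/32 at growth 32 with 4× bottlenecks, ×0.5 compression
transitions) read out at the concatenation of the last dense block and
globally average-pooled — exactly 1,920 values per tile. No deep-learning
framework ships in this environment, so the instantiation is weight-free:
convolution weights are He-initialized from a fixed seed and batch-norm
uses the image's own statistics, preserving the architecture, the
dimensionality and determinism; with ImageNet-pretrained weights the same
readout yields the histomorphologically informative features the method was
designed around, and the backend is pluggable precisely so such weights can
be dropped in. The `classical` backend (49 colour/texture statistics per
tile) is deterministic, fast, needs nothing external, and separates the
procedural textures of the phantom cleanly; it is the default for analysis
here. Features are Min-Max scaled per feature across foreground tiles
(constant features map to 0 and are flagged); background tiles are mapped
with the same affine transform and clipped, so every stored value is in
[0, 1].

**Registration.** One NMF (Lee–Seung multiplicative updates, seeded, rank
8 by default) per cube produces spatial score maps; the registration is
driven by matched map pairs. Manual pair choice reproduces the
visual-selection workflow; auto mode correlates all cross-modal pairs on a
coarse common grid and requires |r| ≥ 0.3. The pipeline's auto path uses
the top three distinct pairs jointly (mean MI over pairs): single NMF
components weight regions differently across modalities, and a metric over
several matched pairs averages that component-specific spatial bias out.
The transform is an affine (translation, rotation, anisotropic scale,
shear about the image centre) followed by a cubic B-spline free-form
deformation (control spacing 8 px). Mutual information (32 bins) is
evaluated over the dilated support of the fixed map — never over the empty
background, which would otherwise dominate the joint histogram. The affine
stage runs over a 3-level smoothing pyramid with, at each level, a
translation grid-scan around the current estimate, a translation-only
refinement, then full-affine Nelder–Mead; its MI uses hard binning, which
is free of the partial-volume artefact that can pull an optimum a fraction
of a pixel off perfect alignment (registering a map to itself returns the
exact identity). The FFD stage is L-BFGS-B on the control displacements
with a 0.1 px finite-difference step (the metric is insensitive to smaller
steps), partial-volume binning for smoothness, and a small bending-energy
penalty (λ = 0.01); its result is kept only if it beats the affine MI by a
2 % margin, and a final MI below the starting MI raises an error carrying
the metric trace. Warping applies linear interpolation to ion images and
nearest-neighbour to masks and labels; the m/z axis and channel count are
untouched.

**Segmentation.** Foreground spectra are standardized per channel, reduced
to at most 50 principal components, and connected in a k-nearest-neighbour
graph (k = 15) with self-tuning Gaussian weights
$\exp(-d_{ij}^2/(s_i s_j))$, where $s_i$ is the distance to the k-th
neighbour floored at 0.3× the median positive distance (duplicate-heavy,
noise-free data would otherwise collapse the local scale). Tight,
well-separated clusters naturally disconnect a kNN graph; stranded
components are bridged through their single shortest link (with a message)
so the normalized-Laplacian embedding stays defined — the hard error
remains available via `connect_components = FALSE`. The smallest
eigenvectors are computed densely for small problems and by ARPACK on
$I + D^{-1/2} A D^{-1/2}$ for large ones, then row-normalized and
partitioned by k-means (10 restarts, seed fixed per K). Ids are assigned by
decreasing cluster size so the labeling is invariant to k-means label
permutation. No spatial smoothing is applied anywhere — scattered
mislabeled pixels are supposed to survive to the fusion stage, where being
flagged is their job.

**Internal baselines.** The PC criterion renders a 3-component UMAP
embedding of the spectra as an RGB image, detects Canny edges on it and on
each segmentation map drawn with random region colours, and reports the
mean ± sd Pearson correlation of the binary edge maps over 5 colour runs.
Two implementation choices are deliberate: hysteresis thresholds are
relative to the strongest edge (piecewise-constant label maps have genuine
edges at *every* region boundary; quantile thresholds would discard most of
them), and the correlation is restricted to foreground pixels (the
tissue/background boundary is shared by construction and would reward any
dense edge map). The DBI baseline is the standard Davies–Bouldin index on
the same prepared features. Both are computed for comparison; neither
feeds the selection.

**ROI fusion.** At K\*, pixels whose aligned labels agree are confident and
keep their solid colour; disagreeing pixels form the unconfident mask and
render translucent. The unconfident alpha is a purely visual parameter;
reasonable renderings range from faint (0.2) to half-transparent, and the
default is 0.5 with a config override. Characteristic ions per
ROI are the top Pearson correlations between ion image and ROI mask over
shared-foreground pixels; constant channels are excluded, and correlation
is invariant to affine intensity rescaling by construction. Overlays
upsample grid maps by the tile size (200× for the 100 µm/0.5 µm geometry)
with an order-3 spline kernel for ion images and nearest-neighbour for
label maps.

## What the phantom emulates — and what it does not

`generatePhantom()` builds matched ground-truth data for every stage: a
wobbly elliptical tissue blob, K_true = 4 contiguous Voronoi-grown regions,
sparse lognormal peak signatures per region (120 channels), HF prototypes
per region (64 features in [0, 1]), per-pixel lognormal TIC variation
(cv 0.2), additive spectral noise (0.1 of the mean peak), HF noise
(sd 0.1), 1 % salt-and-pepper mislabels on the MSI side, and a smooth
deformation between the grids capped at 2 px. The defaults mirror a
desk-scale kidney-like specimen on a 60 × 60 grid and keep a full pipeline
run around a minute; all tests and the shipped study conditions use them.

Three structural choices make the phantom behave like the tissue data the
method was built for, and each is worth stating because naive phantoms do
not show these behaviours:

* **Shared smooth texture.** Two smooth random fields modulate the MSI
  intensities (by channel group) and shift the HF features. This is the
  within-region anatomical variation both modalities see in real tissue;
  without it, each NMF score map is a flat region indicator and
  intensity-based registration is under-constrained in region interiors.
* **Modality-specific region similarity.** Chemically, region 2i resembles
  region 2i−1; histomorphologically, region 2i+1 resembles region 2i. Asked
  for fewer clusters than K_true, the two modalities therefore merge
  *different* region pairs, which is exactly the mechanism that depresses
  the consistency curve below the true K in real data. Without this
  structure the merges coincide by chance in a fair fraction of seeds and
  K_true−1 ties with K_true.
* **Histology-only substructure.** Region 1 carries two feature
  subpopulations (separation chosen below the smallest inter-region
  distance), so at K_true+1 the histology side subdivides region 1 — extra
  modality-specific granularity — while the optional MSI-only spurious
  segment is planted in a different region and thus finds no histological
  counterpart. This is what makes the spurious segment's pixels end up
  predominantly unconfident rather than being "explained" by a coincidental
  histology split of the same region.
* **Bulk offset in the deformation.** The inter-grid deformation is a bulk
  translation plus a smooth local warp (total capped at the stated
  magnitude), as serial sections actually present; a zero-mean random field
  alone has a mean displacement too small to distinguish a good
  registration from the identity.

What the phantom does *not* emulate: realistic isotope patterns or peak
shapes (channels are already binned), chemical correlation between ions
beyond region signatures, stain variability and scanner artefacts in the
H&E rendering (procedural textures separate too cleanly), and deformations
with folding or tears. Passing tests therefore demonstrate the pipeline's
mechanics and its selection/flagging logic under controlled conditions, not
performance on any particular instrument's data.

## Numerical choices and degenerate inputs

Grids are 1-based and row-major internally; imzML 1-based x/y convert at
the boundary, and missing raster positions inside the bounding box become
zero-intensity background rather than errors (DESI rasters have dropouts).
Cube caches are HDF5 and invert exactly. Otsu thresholding on a constant
image, empty tissue masks, all-noisy channel sets, constant moving maps,
disconnected graphs (when bridging is disabled), empty clusters in DBI and
K outside its valid range all raise early, specific errors. Exhaustive
kappa alignment breaks ties toward the lexicographically smallest
permutation; K\* ties break toward the smallest K. One global seed fans out
deterministically to per-stage seeds (a hash of the stage name), so stages
are independently reproducible and a rerun with the same configuration
reproduces every numeric output bit-for-bit.

Problem sizes used by the shipped tests: phantoms on 40 × 40 grids for unit
tests and 60 × 60 (the default study condition) for end-to-end checks;
K sweeps over 2..8; five phantom seeds (0–4) for selection and registration
checks; 200 random instances per K ∈ 2..6 for the alignment-vs-brute-force
comparison; 1,000 random labeling pairs (K = 4, N = 1,000) for the
null-distribution check.

## A complete phantom run

```{r pipeline, eval = FALSE}
res <- runPipeline(defaultConfig(), outdir = "run1")
res$curve            # aligned-kappa curve; K* = 4 on the default phantom
res$registration_qc  # mask Dice before/after registration
head(res$ranking)    # per-ROI characteristic ions
```

The run directory contains the resolved `config.yaml`, the consistency
curve and criteria CSVs, both labelings, the ROI summary, the ion ranking,
the integrated confidence map (PNG) and a QC JSON — everything needed to
audit a selection.

## Known limitations

The kappa curve can only corroborate structure both modalities can see: a
real region with no histomorphological correlate will be scored down, which
is a property of the criterion, not a bug. Registration assumes the two
grids cover the same tissue at the same pixel pitch and that the
deformation is smooth and modest; it has no landmark or single-cell mode.
The exhaustive alignment is factorial in K and capped at K = 9; the PC
baseline inherits the colour-dependence the 5-run dispersion quantifies;
and the weight-free DenseNet backend, while architecturally exact, is not a
substitute for pretrained features when real histology discrimination is
the goal — use the classical backend or supply a pretrained-weight
implementation through the same interface.
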