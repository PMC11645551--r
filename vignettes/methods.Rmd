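---
title: "Methods: weakly supervised super-resolution of spatial gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised super-resolution of spatial gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`supergrid` infers gene expression at 8 × 8 µm superpixel resolution from
two inputs that are routinely available together: a spot-level expression
matrix with its spot geometry (Visium-style: 55 µm capture discs on a
100 µm hexagonal pitch) and the H&E image of the same section. The method
rests on one biological assumption — that histological appearance is
strongly correlated with local gene expression — and one geometric fact:
each observed spot value is, physically, the sum of contributions of the
~40 superpixels under its disc. The network therefore never sees a
superpixel-level label; it is trained so that the *sum* of its superpixel
predictions inside each disc reproduces the observed spot value.

## The multimodal feature map

Images are bilinearly rescaled to a fixed 0.5 µm/px so that a 16 × 16
pixel patch covers exactly one 8 µm superpixel, then zero-padded on the
bottom/right to multiples of the 224 px tile size (pad amounts are
recorded; padded superpixels are forced out of the tissue mask and outputs
are cropped back). Three channel groups are stacked per superpixel:

* **Histology features** (F channels): any extractor satisfying the
  backbone contract — 224 × 224 × 3 tile in, 14 × 14 × F per-patch
  features out, deterministically. Pretrained pathology vision
  transformers fit this contract (with F = 1024, giving C = 1029); the
  shipped `fallbackBackbone()` is a training-free alternative that
  summarises each patch by 12 local statistics (per-channel mean, sd, mean
  horizontal/vertical gradient) expanded to F dims by a seeded random
  projection. It is strictly patch-local, reproducible, and discriminative
  enough for testing and for desk-scale use (default F = 32).
* **Position** (2 channels): `alpha * i/nRows` and `alpha * j/nCols` with
  0-based indices and `alpha = 1`. The index origin is a convention the
  formulation leaves open; we fix 0-based.
* **RGB** (3 channels): non-overlapping 16 × 16 average pooling, values in
  [0, 1].

Histology channels are standardised (zero mean, unit variance over in-mask
superpixels) before stacking. The formulation is silent on channel
scaling; without standardisation the F ≫ 5 histology block numerically
drowns the positional and RGB channels, so standardisation is the default
and a switch (`standardize = FALSE`) preserves the raw behaviour.

The tissue mask is computed per superpixel: grayscale average pooling,
Otsu threshold (tissue = the darker side, the H&E convention), 3 × 3
morphological closing, and removal of connected components smaller than
0.1 % of the grid. No algorithm is named in the original formulation; this
is the standard minimal recipe. A contrast-free image yields an all-false
mask plus a warning.

## The GCN and its training

Each spot spans `D = round(diameter / superpixel)` superpixels
(round-half-up, so 55/8 → 7; minimum 1). All spots share one D × D lattice
graph: nodes in row-major order, each connected to its four nearest
neighbours by physical distance (the von Neumann neighbourhood; border
nodes keep the neighbours that exist). Self-loops are added and the
adjacency normalised symmetrically, `Â = D̃^{-1/2}(A+I)D̃^{-1/2}`. The
plain unnormalised operator that the formulation writes is available
(`normalize = "none"`), as is row normalisation; the symmetric default is
the standard stabilisation for GCN training.

The network is ReLU(Â X W0) → ReLU(Â · W1) → linear head → `elu(x) + 1`,
hidden width 512. ELU alone maps to (−1, ∞), which cannot guarantee the
non-negative expression the method requires; adding 1 is the smooth,
strictly positive fix and is the shipped default.

Training minimises the squared distance between each spot's observed
vector and the column sums of predictions over filtered (in-disc,
in-bounds) nodes, summed over genes and spots — the plain squared sum, no
per-gene averaging. Patches are centered on the superpixel containing the
spot center (block top-left = center − ⌊D/2⌋); border blocks are
zero-padded, padded nodes stay in the graph but never enter the filter.
Whether out-of-disc superpixels should be excluded from the *input* too is
ambiguous in the formulation; we keep the full D × D block as input and
filter only in the loss, matching the stated Filter-then-Sum order.

### Optimisation choices

* **Learning rate 1e-3** (Adam, β = 0.9/0.999). Labels are count sums of
  order 10²–10³ while Adam's per-step parameter movement is bounded by the
  learning rate; at 1e-4 the output head cannot traverse the label scale
  within a few hundred epochs, so 1e-3 is the default.
* **Output head initialised at zero, bias at the mean rate.** W2 = 0 and
  `b = eluInverse(mean label per filtered superpixel)` start optimisation
  at the per-gene mean rate: the first gradient steps fit means, spatial
  structure then enters through the hidden layers. A useful side effect is
  exact symmetry — identical label columns produce bitwise-identical
  prediction columns, which the tests assert. Hidden weights are seeded
  Glorot-uniform.
* **Batching**: 32 spots per step, shuffled each epoch from the config
  seed; per-batch graphs are one block-diagonal sparse operator, so a
  batch is a single dense-matrix chain. 300 epochs with early stopping
  after 50 epochs without improvement. Everything downstream of
  `trainConfig(seed=)` is deterministic; two runs with the same seed give
  bitwise-identical loss histories and predictions.
* A non-finite loss aborts with a diagnostic rather than silently
  continuing.

Whole-slide inference zero-pads the feature map to multiples of D, tiles
it into non-overlapping D × D graphs (exactly the training topology),
predicts each with the shared model, reassembles, crops the padding and
zeroes everything outside the tissue mask. Overlapping-tile averaging is
deliberately not implemented, preserving the stated tiling. The
second-layer activations (512 per superpixel) can be exported the same way
and are the features used for k-means tissue segmentation.

## Benchmark construction from single-cell-resolution data

Two simulation routes mirror how imaging-based data are used as ground
truth:

* **Cells → superpixels**: expression is split by exact footprint/cell
  overlap areas, `p_mn = Σ_k (A_kmn / A_k) c_k`. Footprints are
  axis-aligned boxes (explicit, or equal-area squares centered on the
  centroid when only centroid + area are known), so overlaps are interval
  products and totals are conserved to machine precision. Polygonal
  footprints are out of scope — exact polygon clipping would pull in a
  geometry stack for marginal benefit at 8 µm resolution.
* **Pseudo-Visium**: a spot's value is the sum of cells whose *centroid*
  lies within the disc (all-or-nothing membership; the alternative,
  area-fraction weighting, belongs to the grid partition, not to spot
  capture — and when discs overlap a cell counts only toward the nearest
  spot). From binned grids, the sum runs over grid-unit centers within the
  disc radius; re-aggregation of predictions under observed spots is the
  same arithmetic.

Counts stay on the linear scale end to end: the sum constraint is only
meaningful on a linear scale, so library-size normalisation is off by
default (a switch exists for the input side) and log transforms are left
to downstream metrics or clustering. Highly variable genes are ranked by
the variance of library-size-normalised, log1p counts with lexicographic
tie-breaks — the classic dispersion recipe, since none is named.

## The synthetic benchmark

The generator emulates the statistical structure the method assumes. A
small number of smooth latent factors (Gaussian blob, stripe, gradient,
ring; seeded placement, max normalised to 1) drive both:

* **expression** — gene g's mean field is a convex mixture of the factors
  (seeded Gamma loadings) times a per-gene depth drawn uniformly from
  10–30 counts per superpixel at pattern peak (marker-gene scale of
  imaging panels), observed through Poisson counting noise (truncated
  Gaussian optional); the tissue mask is the inscribed ellipse;
* **histology** — each factor absorbs a distinct hue from a white slide,
  over a uniform pink tissue tint strong enough that tissue/slide is the
  dominant Otsu split (as for real H&E); superpixel colours are upsampled
  16× with seeded texture noise.

Pseudo-Visium spots are aggregated from the noisy truth on a hexagonal
55/100 layout, keeping spots whose disc covers at least one in-mask
superpixel, so spot labels equal in-disc truth sums bitwise. Cell tables
for the Xenium-like route place one cell per in-mask superpixel by default
(one 8 µm superpixel ≈ one cell in dense tissue) with lognormal size
factors and jittered centroids.

What the generator does **not** emulate: realistic H&E morphology (nuclei,
texture at sub-patch scale), stain variation, segmentation errors,
platform-specific noise (dropout beyond Poisson, diffusion between spots),
or any imperfect image/expression coupling — here histology is informative
of expression *by construction* (the tests assert a linear probe from
pooled patch features to each latent field reaches R² ≥ 0.5). Passing
recovery tests therefore shows the machinery works when its core
assumption holds; it does not quantify performance on real tissue.

## Evaluation

Per gene, both 2-D maps are min–max normalised over the mask before RMSE,
MAE and SSIM — the formulation reports scale-free magnitudes but no
formula, and min–max over masked entries is the simplest choice consistent
with them. Pearson correlation is computed on raw masked values (it is
affine-invariant anyway). SSIM uses the standard 11 × 11 Gaussian window
(σ = 1.5), K1 = 0.01, K2 = 0.03, data range 1, with reflection padding at
borders and the SSIM map averaged over masked centers. Genes constant over
the mask are flagged and excluded from summary medians/means; zero
variance flags PCC as undefined rather than producing NaN. TLS scoring
averages the min–max-normalised maps of the supplied marker genes (the
marker list is an input, not hard-coded). Tissue segmentation runs k-means
(10 restarts, seeded) on the masked GCN features and relabels clusters by
decreasing size for determinism.

The reference point for recovery is **uniform disaggregation** — each spot
value spread equally over its disc superpixels, zero elsewhere — the
baseline any super-resolution method must beat.

## Problem sizes

The shipped benchmark runs at desk scale by choice: 96 × 96 superpixels
(768 × 768 µm), 25 genes, 3 latent factors, ~60 in-tissue spots, fallback
backbone with F = 32, 300 training epochs. A full
simulate–featurise–train–infer–evaluate cycle takes on the order of a
minute on one CPU; oracle-equivalence tests use instances of at most
D = 5, 64 × 64 maps and 500 cells.

## Known limitations

* The fallback backbone captures colour and first-order texture only; with
  it, performance reflects the pipeline, not what a pretrained pathology
  transformer would extract from real H&E. Any conforming backbone can be
  plugged in via the contract.
* One shared lattice graph per D means spots are assumed identical in
  geometry; platforms with variable spot sizes would need per-spot graphs.
* Non-overlapping inference tiles can leave faint seams at tile borders;
  overlapping-tile averaging was deliberately not added (fidelity to the
  stated procedure).
* Weak supervision constrains sums, so within-disc spatial detail is
  identified only through the image features; where histology is
  uninformative the model falls back to smooth disc-consistent fields.
* Multi-section joint training and cross-section domain adaptation are out
  of scope; transfer inference (another section's feature map through a
  trained model) works mechanically but is unvalidated here.
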