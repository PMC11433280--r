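---
title: "Methods: a coarse-to-fine multi-task cascade for nodule patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-to-fine multi-task cascade for nodule patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package implements a three-network cascade for 2D CT nodule patches
that couples segmentation and benign/malignant classification through
*prediction distillation*: one network's prediction is handed to the next
networks as an extra input channel, rather than sharing gradients.

1. **Coarse segmentation network.** An encoder--decoder semantic
   segmentation model: an aligned-Xception-style backbone in which every
   down-sampling step is a stride-2 depthwise separable convolution (there
   is no max pooling anywhere in the graph), an atrous spatial pyramid over
   the deepest features, and a decoder that fuses a stride-4 low-level
   feature map. The prediction head is a 1×1 convolution with a single
   output channel and a sigmoid — it replaces the usual final 3×3
   convolution — followed by bilinear upsampling to the input resolution.
2. **Fine segmentation network.** Identical structure, every shared
   parameter initialised as a copy of the trained coarse network, plus a
   *fusion layer*: the coarse probability map is area-downsampled onto the
   deepest feature grid, concatenated as one extra channel, and fused back
   to the original channel count by a 1×1 convolution, batch normalisation
   and ReLU. The fused features feed the pyramid and decoder.
3. **Classification network.** An Xception-style classifier whose exit-flow
   down-sampling stage is removed (so small nodules keep their resolution)
   and whose last two separable convolutions are dilated with rate 2 and
   padding 2 to recover the receptive field; global average pooling,
   dropout and a single sigmoid logit produce a malignancy probability.
   With mask guidance the coarse probability map enters as a fourth input
   channel whose first-layer kernels are initialised as the mean of the
   three RGB kernels, so RGB-pretrained weights can be carried over
   unchanged.

Training is *staged*: the coarse network is trained once and frozen, its
probability maps are precomputed for every manifest row, and the fine and
classification networks train against those fixed maps. We read the
original pipeline's figure as staged rather than joint optimisation; it
also makes the guidance a pure information channel, so a weak first stage
cannot destabilise later stages through gradients.

## Losses

Segmentation networks minimise a hybrid loss

$$L_{seg} = L_{Dice} + \gamma\, L_{Rank},$$

with $L_{Dice} = 1 - 2\sum_i P_i G_i / (\sum_i (P_i + G_i) + \varepsilon)$
computed per image and averaged over the batch. The rank loss is an online
hard-pixel scheme: after each forward pass, background pixels are ranked by
their error $P_i$ and foreground pixels by $1 - P_i$, the $K$ worst of each
region are selected per image, and every background/foreground pair is
hinged:

$$L_{Rank} = \frac{1}{K_0 K_1} \sum_{i=1}^{K_0} \sum_{j=1}^{K_1}
  \max\left(0,\; H^0_i - H^1_j + margin\right).$$

Defaults are the reference operating point $\gamma = 0.02$, $K = 20$,
$margin = 0.3$. Decisions the loss definition leaves open, resolved here:

* **Error definition**: per-pixel error is $|P - G|$, so background error is
  $P$ and foreground error is $1 - P$.
* **Selection scope**: hard pixels are selected per image; per-image rank
  losses are averaged over the batch.
* **Truncation**: a region smaller than $K$ contributes all of its pixels,
  and the normaliser is the actual $K_0 K_1$, not $K^2$.
* **Empty regions**: an image with no foreground or no background
  contributes zero rank loss, so degenerate patches cannot poison training.
* **Ties**: broken by pixel scan order — selection is deterministic.
* **Gradients**: selection is a hard choice that carries no gradient;
  gradients flow only through the selected probability values (the standard
  hard-example-mining contract). $\varepsilon$ defaults to $10^{-6}$.

The classifier minimises binary cross-entropy on its sigmoid output.

## Metrics

Segmentation uses the set-cardinality formulations: Dice
$2|S\cap GT|/(|S|+|GT|)$, Jaccard $|S\cap GT|/|S\cup GT|$, pixel accuracy
$(I - |S\cup GT| + |S\cap GT|)/I$, recall $|S\cap GT|/|GT|$ and specificity
$(I - |S\cup GT|)/(I - |GT|)$, evaluated per image after binarizing the
probability map at 0.5 (with $\ge$ at the boundary) and averaged
unweighted. Dice and Jaccard satisfy $DI = 2\,JA/(1+JA)$ identically, which
the tests verify both algebraically and against reported reference Dice/Jaccard
pairs. When predicted and true masks are both empty, Dice and Jaccard are
defined as 1; an empty or all-foreground *ground truth* makes recall or
specificity undefined and is reported as an error naming the metric.
Classification uses accuracy, sensitivity, specificity and rank-based AUC
(Mann--Whitney with half-credit ties, so it is invariant under monotone
score transforms).

## Dataset curation rules

Per-nodule reader scores (1--5) are aggregated by their median, with halves
rounded up; the aggregate decides benign (≤ 2), malignant (≥ 4) or excluded
(= 3). Nodules are also excluded when the diameter is outside 3--25 mm,
when the identity record is illegible, or when fewer than 2/3 of the
readers delineated the nodule. Pixel ground truth is a majority vote (a
pixel is foreground when ≥ 50% of readers marked it); both thresholds are
exposed as arguments because the consensus convention is a judgement call.
Patches are cropped 64×64 around the mask centroid with zero padding at
borders, optionally augmented 9× (random centre-crop at 50--100% resized
back, 110% zoom, horizontal and vertical flips, drawn uniformly per copy
under a seed), resampled to 224×224 (bilinear for images,
nearest-neighbour for masks so they stay binary), and split 6:2:2 by
*source image*, stratified by label, so augmented copies can never leak
across splits. Images enter as 8-bit 3-channel PNG in [0, 1]; masks as
8-bit single-channel PNG with {0, 255} read as {0, 1}.

## The synthetic generator

`synth_config()` / `generate_dataset()` emulate the statistical structure
the cascade needs without any external data: bright blobs on a noisy
background, where the *benign* class is a low-eccentricity ellipse and the
*malignant* class a star-shaped region
$r(\theta) = r_0 (1 + a \max(0, \sin(m\theta + \phi)))$. The mask is the
exact generating region; the image is the mask times a drawn intensity,
Gaussian-blurred (fuzzy boundary), plus Gaussian background noise,
replicated to three channels. Intensity ranges are identical for the two
classes, so brightness carries almost no class signal and the label is
carried by boundary shape — the synthetic analogue of radiological
spiculation.

Default parameters and why:

* `image_size = 64`, radii 8--16 px: the patch geometry of the curation
  rules, with nodules occupying a realistic fraction of the patch.
* `spiculation_amplitude = 0.7`, `spiculation_lobes = 5`: spikes of 5--11
  px. Spiculation must remain visible after segmentation at the decoder's
  stride-4 boundary resolution; finer spikes produce shapes whose predicted
  masks are indistinguishable from smooth ones, i.e. a synthetic task
  without the shape-borne class signal the generator exists to provide.
  Strongly spiculated malignant exemplars of this kind are radiologically
  typical.
* `background_noise_sd = 0.2` over a 0.2 background level: localisation
  and denoising are non-trivial (a thresholded raw image does not recover
  the shape), which is what makes a distilled location prior worth having.
* `blur_sd = 1` px: fuzzy boundaries, the declared hard case for
  segmentation.
* Compactness ($4\pi\,area/perimeter^2$ on the digital 4-neighbour
  perimeter) separates the two classes' masks with a standardised mean
  difference well above 2, the generator's learnability guarantee, which
  the tests assert over seeded samples.

What the generator does **not** emulate: CT texture, vessels and pleural
attachments, intensity semantics of Hounsfield units, multi-reader
delineation variability, and any correlation between nodule size and
malignancy (radii are drawn from the same range for both classes on
purpose). Passing desk-scale tests therefore demonstrates that the
implementation learns and that guidance helps under controlled conditions
— not clinical performance.

## Desk-scale experimental profile

`desk_profile()` fixes the configuration used by the package's own
experiments and the acceptance script; everything is overridable for
larger runs.

* **Width multiplier 0.125, one middle-flow block, 64×64 inputs.** Channel
  counts floor at 8. Full-size defaults (width 1, 16/8 middle blocks,
  224×224 inputs) build the full reference topology.
* **Dataset: 200 train / 50 val / 50 test source images** (150 per class,
  split 4:1:1).
* **Learning rates 2e-3 (segmentation) and 4e-3 (classification), constant.**
  The reference 1e-4 belongs to pretrained full-size backbones trained for
  100 epochs; from-scratch 0.125-width networks on short schedules need a
  proportionally larger constant step. No schedule is used (only an initial
  rate is specified in the reference procedure).
* **Epochs: 8 (segmentation stages) / 10 (classifier); batch 16 / 4.** The
  segmentation networks receive dense per-pixel supervision and converge in
  a few hundred steps; the classifier sees one bit per image, so the desk
  profile trades batch size for optimisation steps (500 at batch 4).
* **On-the-fly flips** during training, applied identically to image, mask
  and guidance channel — a cheap stand-in for the 9× offline augmentation
  at desk scale (the offline scheme is implemented and tested in the data
  module). Dropout 0.5 before the classifier logit, as in the reference
  classifier topology.
* **Guidance channel binarized at 0.5 for the classifier** (a documented
  switch; the full-scale default passes the raw probability map). At 64×64
  the soft map's blur smears exactly the thin-spike boundary signal that
  separates the classes; thresholding restores a crisp shape channel.
* **Model selection**: best validation Jaccard (segmentation) / accuracy
  (classification), evaluated each epoch; no early stopping by default.

With this profile one full cascade — generation, three trainings, mask
precomputation, evaluation, plus the unguided classifier ablation arm —
runs in roughly two minutes on one CPU core; the acceptance suite repeats
it over ten seeds.

### Ablation contrasts

Two paired contrasts mirror the reference ablations: segmentation is
compared between the coarse-only output and the guidance-fused fine output
(the with/without-fine-stage contrast), and classification between the
4-channel mask-guided and the 3-channel unguided classifier. A third arm,
a fine network trained with an all-zero guidance channel
(`train_fine(use_guidance = FALSE)`), is implemented and tested; at desk
scale it is statistically indistinguishable from the guided arm, because
both start from the trained coarse weights and the guidance channel adds
no information the encoder does not already have — a scale artefact worth
knowing about, which is why the coarse-versus-fine contrast is the one the
acceptance suite measures.

## Numerical choices

* Weight initialisation: truncated normal (2 SD) with He scaling for all
  convolutions; fusion layer and prediction head start random by design.
  All randomness flows from the config seed.
* Batch norm: per-channel batch statistics in training, running statistics
  (momentum 0.1) at inference; checkpoints store both parameters and
  running statistics, plus the full build spec, and restoring refuses a
  mismatched spec.
* Bilinear resizing uses half-pixel centres with clamped borders; its
  backward pass is the exact adjoint (tested). Mask downsampling onto the
  feature grid uses non-overlapping area averaging, as the probability map
  is a smooth field.
* The coarse maps are stored as 8-bit PNG (quantisation 1/255), which is
  below every effect size the pipeline measures.
* Class activation maps: with a global-average-pool + single-logit head the
  gradient of the logit with respect to a feature channel is constant over
  space, so the gradient-weighted map reduces to the ReLU of the
  head-weighted feature sum; maps are min--max normalised per image (flat
  maps map to zero, never NaN) and bilinearly upsampled.

## Known limitations

* The built-in CNN engine is CPU-only, dense, double-precision R/C++; it is
  sized for desk-scale experiments and ships no pretrained weights — the
  4th-channel initialiser is the hook through which external RGB weights
  would enter.
* Real-data ingestion (DICOM, reader XML) is out of scope; the PNG/CSV
  contracts are the interface an adapter would target.
* The synthetic task's difficulty is controlled, not clinical; conclusions
  transfer as implementation correctness and qualitative ablation
  direction, not as expected real-data scores.
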