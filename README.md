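# nodulecascade

Multi-task coarse-to-fine segmentation and benign/malignant classification
of lung-nodule CT patches, as a tested R package.

Computer-aided diagnosis of lung cancer rests on two coupled tasks over CT
patches: delineating the nodule (segmentation) and calling it benign or
malignant (classification). This package implements a cascade that couples
them by **prediction distillation**: a coarse segmentation network produces
a nodule probability map, and that map — not its gradients — is handed
onward as a prior location channel, to a fine segmentation network (fused
with the deepest encoder features by a 1×1 convolution + batch norm + ReLU
*fusion layer*) and to the classifier (concatenated as a fourth input
channel whose first-layer kernels start as the mean of the RGB kernels).
It is aimed at researchers who want a transparent, fully inspectable
reference implementation of this cascade — including a compact,
gradient-checked CNN engine (depthwise-separable convolutions everywhere a
pooling layer would otherwise sit) — that trains end to end on one CPU
using a built-in synthetic patch generator, with no external dataset or
GPU.

## The model

Segmentation networks are encoder–decoder models (aligned-Xception-style
backbone, atrous pyramid, stride-4 decoder, 1×1 sigmoid head) trained with
a hybrid loss

```
L_seg = L_Dice + γ · L_Rank
L_Dice = 1 − 2 Σ P_i G_i / (Σ (P_i + G_i) + ε)
L_Rank = (1 / K0·K1) Σ_i Σ_j max(0, H0_i − H1_j + margin)
```

where `H0` are the K highest-error background pixels (largest `P`), `H1`
the K highest-error foreground pixels (smallest `P`), selected per image
after each forward pass — an online hard-pixel scheme that concentrates
supervision on boundary pixels. Defaults: `γ = 0.02`, `K = 20`,
`margin = 0.3`. The classifier is an Xception-style network without the
exit-flow down-sampling (its last two separable convolutions are dilated,
rate 2 / padding 2) trained with binary cross-entropy.

Evaluation uses the set-cardinality metrics `DI = 2|S∩GT|/(|S|+|GT|)`,
`JA = |S∩GT|/|S∪GT|` (so `DI = 2·JA/(1+JA)` identically), pixel accuracy,
recall and specificity for segmentation, and ACC/SEN/SPE plus rank-based
AUC for classification.

## Worked example

One full desk-scale experiment — generate 300 synthetic 64×64 patches
(spiculated vs smooth blobs, 200/50/50 train/val/test), train the coarse
network, distil its masks into the fine network and the classifier, train
the unguided classifier for comparison, and evaluate on the held-out test
split:

```r
library(nodulecascade)
res <- run_cascade_experiment(seed = 1)
cat(sprintf("fine DI %.3f (coarse %.3f) | ACC %.2f (unguided %.2f) | AUC %.3f\n",
            res$seg$di, res$seg_coarse$di,
            res$cls$acc, res$cls_unguided$acc, res$cls$auc))
```

```
fine DI 0.930 (coarse 0.887) | ACC 0.98 (unguided 0.56) | AUC 0.997
```

Reading: on held-out synthetic patches the guidance-fused fine network
improves the Dice overlap over the coarse mask (0.930 vs 0.887), and the
mask-guided classifier separates spiculated from smooth nodules almost
perfectly (ACC 0.98, AUC 0.997) while the same classifier without the
coarse-mask channel stays near chance under the same 10-epoch budget —
the qualitative signature of prediction distillation. The run takes about
two minutes on one CPU core.

The building blocks are exported individually
(`dice_loss`, `rank_loss`, `select_hard_pixels`, `segmentation_metrics`,
`roc_auc`, `label_nodule`, `consensus_mask`, `augment`, `split_manifest`,
`build_coarse_segnet`, `build_fine_segnet`, `build_classnet`,
`train_coarse`, `precompute_masks`, `train_fine`, `train_class`,
`cascade_predict`, `compute_cam`, …); a thin command-line front end with
`generate / train-coarse / precompute-masks / train-fine / train-class /
evaluate / predict / cam` subcommands lives at
`inst/cli/nodulecascade.R`. The methods vignette
(`vignettes/cascade-methods.Rmd`) documents the model, the loss and
metric conventions, the synthetic generator and every defaulted choice.

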