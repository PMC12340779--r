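---
title: "Semantic-guided vision-language modeling of lung nodule malignancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic-guided vision-language modeling of lung nodule malignancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`noduleclip` implements a contrastive vision-language pipeline for one-year
lung-cancer risk prediction from chest CT. The central idea is to use
radiologist semantic features — margin, consistency, shape, and internal and
external findings — as *training-time* supervision for an imaging model, so
the image encoder is pulled toward clinically meaningful structure rather
than acquisition shortcuts, while inference needs only the image.

A nodule is represented in 2.5D: the CT volume is resampled to 1 mm
isotropic spacing, windowed to HU $[-1000, 500]$ and rescaled to $[0,1]$,
cropped to a 50 mm cube about the nodule centroid, and sectioned on the nine
symmetry planes of the cube (three axis-aligned, six diagonal), each sampled
at 1 mm on a $50\times50$ grid through the cube centre. Each section is
resized to $224\times224$, replicated to three channels, and standardized
with the pretrained encoder family's channel constants.

The nine views pass through a vision transformer; per-view embeddings are
pooled by non-gated attention-based multiple-instance learning,

$$a_k = \mathrm{softmax}_k\!\left(w^\top \tanh(V h_k)\right), \qquad
  z = \sum_k a_k h_k,$$

and projected to a 256-d embedding $I_i$. The semantic record is rendered
into report-like text (findings + impression), tokenized, encoded by a text
transformer, and projected to $S_i$. Training aligns the two with the
symmetric InfoNCE objective

$$\mathcal{L}_{\mathrm{img}} =
 -\tfrac1B \sum_i \log
 \frac{\exp(\mathrm{sim}(I_i,S_i)/\tau)}{\sum_j \exp(\mathrm{sim}(I_i,S_j)/\tau)},$$

its text-direction counterpart (denominator over images), and their average
as the contrastive loss; $\mathrm{sim}$ is cosine similarity and $\tau$ is a
learnable temperature initialized at 0.03 and clamped to $[10^{-3}, 1]$.
Each branch additionally carries a linear prediction head trained with
class-weighted cross-entropy on the one-year diagnosis; the three losses are
equally weighted. At inference only the image branch is evaluated; patient
risk is the maximum over that patient's calibrated nodule probabilities, and
predictions are averaged over the cross-validation fold models after
per-fold Beta calibration.

Parameter-efficient adaptation inserts rank-2 low-rank adapters into every
query/key/value projection of both transformers: the effective weight is
$W_0 + \frac{\alpha}{r} BA$ with $B$ zero-initialized (so injection is the
identity), $\alpha = 1$, $r = 2$, adapter-input dropout 0.25, and the base
weights frozen. At ViT-B/32 dimensions the trainable set — adapters, the two
256-d projection heads, the MIL head, the prediction heads, and $\tau$ — is
0.338% of all parameters by exact enumeration.

## Design choices the architecture leaves open

Several details are not fixed by the protocol this package follows; the
choices here are deliberate and recorded once:

* **The nine planes.** Only "nine planes through the centroid" is specified.
  We use the cube's nine symmetry planes with a deterministic in-plane frame
  (first axis: normalized projection of the lowest-index world axis not
  parallel to the normal). The sampling grid is symmetric about the cube's
  continuous centre, which makes reflections of the crop act on the view set
  as an exact permutation plus dihedral transform — a property both the test
  suite and the fast augmentation path exploit. Diagonal views keep 1 mm
  sampling (cropping corners rather than rescaling) so all views share one
  physical scale.
* **Where MIL sits.** Pooling operates on the encoders' standard
  final-projection outputs (512-d at ViT-B/32), i.e. between encoder and the
  256-d projection head. This matches the published trainable fraction;
  pooling the 768-d pre-projection features would push the trainable set to
  0.403%.
* **Report text.** The external generative-model step is replaced by a
  deterministic templater (findings: one sentence per observed feature,
  negatives included; impression: noun phrase of margin + consistency +
  shape plus present findings). A `text_provider` hook accepts any
  alternative generator. Ordinal harmonization of the public
  screening-cohort annotations uses explicit thresholds (spiculation or
  lobulation $\ge 4$; margin $\le 2$ ill-defined; texture 1–2 / 3 / 4–5 as
  pure ground glass / part-solid / solid; sphericity $\le 2$ / 3 / $\ge 4$
  as irregular / ovoid / round); these are stand-ins, not reconstructions of
  an unpublished table, and are overridable.
* **Calibration order.** Beta calibrators are fitted per fold on that fold's
  validation predictions (the only unbiased in-training choice), applied to
  nodule probabilities, then the patient maximum is taken and folds are
  averaged.
* **Zero-shot softmax** uses the learned $\tau$.
* **Rarity upsampling** uses weight $=\max$ over a nodule's observed feature
  values of inverse value-frequency, frequencies floored at 0.5% so a
  single-exemplar class cannot dominate, raised to a sampler temperature,
  normalized to mean 1. The temperature defaults to 1 (full
  inverse-frequency weighting); the phantom benchmark uses 0.5 because on a
  256-nodule training fold full weighting concentrates a double-digit share
  of all draws on a handful of rare-feature nodules, which measurably harms
  generalization of the image branch.

## Numerical implementation

The encoders, adapters, MIL pooling, and all losses are implemented directly
in R with hand-derived reverse-mode gradients over BLAS matrix operations;
the test suite verifies every gradient path against central finite
differences (tolerance $10^{-4}$ relative on the loss closed forms, $10^{-3}$
on sampled coordinates of the full model). Attention over the many
nine-view blocks is computed column-by-column over key positions, which
keeps the block-diagonal score matrix in full-height vectorized operations.
AdamW follows the published recipe (learning rate $10^{-4}$, weight decay
0.1, batch 16) with decoupled decay on weight matrices only. Three standard
stabilizers that the protocol does not discuss are added and exposed in
`train_config()`: linear warmup (2 epochs) into cosine decay, global
gradient-norm clipping at 1.0, and depth-scaled initialization of residual
output projections. Degenerate inputs are handled explicitly: a non-finite
loss aborts training with the offending component named; single-class
batches cannot arise in the contrastive loss (batch size $\ge 2$ enforced);
AUROC/AUPRC error on single-class inputs rather than returning a default.

## The phantom cohort

Real screening cohorts are restricted, so the package ships a seeded phantom
generator that emulates their *structure*: a CT-like volume (Gaussian lung
background, $-850 \pm 40$ HU) containing one nodule whose rendered
morphology is a deterministic-plus-noise function of a sampled semantic
record — consistency sets interior attenuation (solid $\approx +30$ HU, pure
ground glass $\approx -620$ HU, part-solid a shell/core composite),
spiculation adds Poisson(8) radial spikes of 2–6 mm, lobulation low-order
angular lobes, an ill-defined margin widens the edge blend to
$\sigma = 1.5$ mm, and eccentric calcification, cyst-like spaces, and a
pleural plate render as localized HU structures. Marginals are shaped like
the published class percentages (73% solid, 9% pure ground glass, 67%
smooth margins, rare internal findings, 71% missingness in airway cutoff).
Labels are drawn from a declared logistic model on the semantic covariates
plus a standardized radius term — never from the pixels — so any image-based
predictive skill must be earned by reading the rendered morphology. Two
features of real data are deliberately *not* emulated: anatomical context
(airways, vessels, lobar structure) and inter-reader annotation noise.
Passing the phantom benchmark therefore demonstrates that the pipeline
learns planted morphology–outcome structure end to end; it says nothing
about absolute clinical performance.

One covariate (vascular convergence, coefficient $+1$) is intentionally
invisible in the rendering, and labels are Bernoulli draws, so the
image-visible Bayes AUROC on a 400-case cohort is about 0.85 — the natural
ceiling for the benchmark below.

## Desk-scale study sizes

All tests run on the `tiny` preset: vision input 56 (patch 28, width 32,
depth 2, 4 heads), a matching text tower over the package's whitespace
tokenizer, 256-d projection heads, MIL hidden size 128. The benchmark
cohort is 400 phantoms at $32^3$ voxels, split 20% held-out patients, with
two of the five cross-validation folds trained for 24 epochs (learning rate
$2\times10^{-3}$ — random initialization tolerates and needs a larger step
than adapter tuning of pretrained weights — with the warmup, cosine,
clipping, and view-space augmentation defaults, sampler temperature 0.5).
Randomly initialized encoders are trained in `full` tuning mode without
adapters; `lora` mode exists for adapter tuning of loaded pretrained
weights, and `probe` mode trains heads only. Training-time augmentation on
precomputed view datasets applies exact volumetric flips through the
view-set symmetry plus Gaussian noise (sd 0.02) and log-gamma contrast; the
full volumetric policy (centroid jitter up to 5 mm, rotations up to 10
degrees) is available through `augment_crop()` when training from volumes.

Three further training-loop behaviours are worth knowing when reproducing
phantom studies. Checkpoint selection scores the trailing three-epoch mean
of validation AUROC rather than single epochs (validation folds of a few
dozen patients make the per-epoch AUROC noisy, and a single spike would
otherwise freeze an unconverged checkpoint), restricted to the converged
tail of the schedule. Validation and checkpoints use an exponential moving
average of the trainable weights (decay 0.99 per step). And if an attempt's
validation AUROC has not cleared 0.58 within 8 epochs, training restarts
from a freshly seeded initialization inside the same epoch budget — small
randomly initialized towers occasionally start in a basin the optimizer
does not leave. All three are deterministic under the run seed.

## What the phantom views can and cannot show

A consequence of the 2.5D representation worth stating explicitly: the
phantom's spiculation is rendered as thin (about 1 mm) radial strands, and a
planar section through the nodule centre intersects such a strand only
where the strand lies near that plane — in the nine views, spiculation
appears as sparse marginal dots rather than the radiating strands a 3D
reader sees. Margin classes are therefore substantially harder to recover
from the nine sections than from the volume, while consistency (interior
attenuation) transfers essentially losslessly. This asymmetry shows up
throughout the test suite: zero-shot consistency discrimination on held-out
phantoms is near-perfect, whereas the end-to-end malignancy AUROC — whose
label model is driven mainly by margin covariates, an invisible covariate
(vascular convergence), and Bernoulli outcome noise — sits near the ceiling
of what margin-geometry features support in this representation.

## Known limitations

* The toy tokenizer is a whitespace vocabulary over the schema; pretrained
  byte-pair-encoding weights are an external plug-in, not shipped.
* DICOM series input is not supported in this build (no reader available);
  NIfTI volumes and CSV manifests are the supported interchange.
* The phantom benchmark's AUROC is bounded by design (invisible covariate +
  Bernoulli labels) and its absolute value is not comparable to clinical
  cohort results.
* Gated MIL, multi-year risk horizons, and alternative calibrators beyond
  the Beta family are out of scope.
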