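---
title: "Weakly supervised slide classification with attention MIL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised slide classification with attention MIL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wsimil)
```

# The problem

Some histological findings — the motivating example is microvascular
invasion (MVI) in hepatocellular carcinoma — are diagnosed per
*patient*, from multiple whole-slide images (WSIs), without anyone
marking where on any slide the evidence sits. Supervision is therefore
*weak*: a binary label attaches to a patient, every slide of that
patient inherits it, and a slide of a positive patient may not contain
the finding at all. wsimil implements the full modelling pipeline for
this setting: pyramid tiling, background filtering, tumor/peri-tumor
segmentation, bag sampling, an attention-pooling multiple-instance
network per magnification with checkpoint ensembling, hierarchical
score aggregation, clinical tissue-limitation simulators, and
interpretability tools.

# The model

## Bags and labels

Each WSI is divided into non-overlapping 512 x 512 pixel patches at
5x, 10x, 20x and 40x. Patches with strictly more than 50% background
coverage are excluded (a patch at exactly 50% is kept). A *bag* is a
fixed-size sample of tumor-area patches from one slide — 8 patches at
5x, 32 at 10x, 64 at 20x — labelled with the patient's status
regardless of what the individual patches show. Slides with fewer
tumor patches than the bag size are padded by sampling with
replacement, which keeps the attention layer's shape static. 40x is
supported by the tiling and segmentation layers but excluded from the
prediction model; its predictive performance does not justify the
cost, and `fit_mil_classifier()` refuses it.

## Attention pooling

Instance features $h_k \in \mathbb{R}^d$ come from a feature
extractor; bags are pooled with gated attention
$$a_k = \frac{\exp\{w^\top(\tanh(V h_k) \odot \sigma(U h_k))\}}
             {\sum_j \exp\{w^\top(\tanh(V h_j) \odot \sigma(U h_j))\}},
\qquad z = \sum_k a_k h_k,$$
and a fully connected head maps $z$ to a bag score
$\sigma(w_c^\top z + b)$. The weights $a_k$ sum to one and the whole
forward pass is invariant to instance order; both properties are
tested exactly. Gated (rather than plain tanh) attention is a design
choice — the underlying MIL framework admits either and the gated form
is the stronger default.

## The backbone, and why it is small

The built-in feature extractor is a three-block CNN (3x3
convolutions with channels 8/16/32, ReLU, 2x2 max pooling, global
average pooling) over a 16 x 16 x 3 area-average downsample of each
512 x 512 patch, trained end to end with the attention head. Two
choices deserve comment.

*Input downsampling.* The class-conditional texture signal this
package's synthetic cohorts plant — and, more generally, any signal
carried by stain intensity and coarse texture — survives area
averaging, while 512 x 512 inputs would make desk-scale end-to-end
training in R unworkable. The downsampled tensors are cached once per
patch at preparation time, so training touches no pixel data. The
backbone contract (`instance_features()`) is pluggable; a pretrained
large-scale extractor can be substituted where the compute exists,
and nothing else in the pipeline changes.

*Edge padding.* Convolutions use replicate (edge) padding rather than
zero padding. On a 16 x 16 input the final 4 x 4 feature maps are
mostly "border", and zero padding would inject a strong frame
artifact into every class-activation map; with edge padding a
spatially constant input provably yields spatially constant maps,
which is asserted in the tests.

Training minimises bag-level binary cross-entropy with Adam
(learning rate 2e-3 by default), one optimiser step per bag. Training
bags are freshly resampled every epoch — the sampling acts as
augmentation; whether the original method fixed or resampled its bags
is not stated, so resampling is declared here as the default.
Fine-tune bags are fixed once so the selection metric is stable.

## Checkpoint selection and ensembling

A fine-tune set (a held-aside part of the training pool, split by
patient) is scored every epoch. The *overfitting point* is the first
epoch at which the fine-tune loss, smoothed with a trailing 3-epoch
mean, has risen for 3 consecutive epochs; the ensemble keeps the five
epochs with the best fine-tune AUC strictly before that point, ties
resolved towards the earlier epoch. No published rule exists for
"before overfitting", so this operationalisation is the package's
own; it is deterministic and unit-tested on synthetic loss curves.
When fewer than five epochs precede the overfitting point the five
best epochs overall are used and the ensemble is flagged.

## Score aggregation

Scores average up a strict hierarchy: five checkpoints → one ensemble
score per magnification; three magnification scores → one WSI score;
all WSI scores of a patient → the patient score; predicted positive
iff the patient score is **at or above** 0.58 (the published
best-accuracy cutoff, with its own "≥ 0.58 as positive" tie
convention). Every level is an unweighted mean, so the patient score
equals the grand mean of all checkpoint scores when counts are
balanced — an identity the acceptance tests check to 1e-9. A slide
with no tumor patches at some magnification is scored from the
remaining magnifications and flagged.

# Tissue segmentation

Bags are restricted to tumor-area patches because models trained on
tumor-area input outperform peri-tumor and whole-slide input — the
synthetic cohorts reproduce this by construction (see below). The
segmenter is a per-patch binary classifier sharing the backbone
architecture with a logistic head; patch ground truth comes from
pixel masks by majority vote (> 50% tumor pixels ⇒ tumor). An *oracle
segmenter* that reads the synthetic masks directly is provided so
that MIL-level tests do not compound segmenter error. The published
segmentation network itself is unspecified, so the small CNN here is
a declared substitute, and 40x segmentation is supported but unused
by the final model.

# The synthetic cohort generator

`generate_cohort()` builds the study conditions every test runs
under: `n_patients = 60` patients, 2–4 slides each, prevalence 0.5
(the motivating cohort is near-balanced at 51.4% positive), slides of
4096 x 4096 px at the 40x-equivalent base — the smallest size that
still yields a full 512-px patch at 5x — with `tumor_fraction = 0.6`
so the single 5x patch is usually majority-tumor, `effect_size = 2`,
`noise_sd = 0.05`, and a thin background border (~12% of area) that
the HSV white-glass detector recognises.

Each slide has a contiguous irregular tumor blob inside tissue;
texture is built from per-class base colours (eosin-pink peri-tumor,
purple tumor), slide-level stain jitter (sd 0.02, shared by all
patches of a slide — the nuisance that forces models to generalise
across slides), blob noise at a class-specific granularity, and fine
grain. Positive patients' tumor regions (or a contiguous
`signal_fraction` subregion) additionally get a per-channel mean
shift of `effect_size * (0.005, -0.030, 0.010)` and a
`1 + 0.25 * effect_size` blob-scale factor. At `effect_size = 0` the
two classes' tumor textures are drawn from one distribution;
peri-tumor texture is identical across classes at every effect size,
so only tumor-area bags can carry information — the ablation the
pipeline must reproduce.

One geometric subtlety matters at desk scale. Patch class labels are
majority votes, so a "peri-tumor" patch may contain up to half tumor
pixels, and on small slides the patches are large relative to the
tumor boundary: if the signal were rendered on every tumor pixel it
would bleed into boundary patches of the peri-tumor *pool* and make
the peri-tumor arm of the ablation spuriously predictive (on real
gigapixel slides patches are tiny relative to regions and the bleed
is negligible). The renderer therefore applies the class-conditional
shift only within patches whose majority class at the magnification
being rendered is tumor; tumor pixels inside majority-peri-tumor
patches get the baseline tumor texture. The planted region mask is
unchanged — only the signal's rendered support is restricted — and
the guarantee becomes exact at the patch level, which is the level at
which bags sample.

*Rendering is lazy and deterministic.* A slide object stores only a
64 x 64 region field, its stain jitter and a seed; pixels of any
level region are a pure function of (slide seed, level, origin), so
cohorts cost kilobytes until pixels are requested and identical
config + seed gives bit-identical rasters. A consequence, declared
openly: pyramid levels share their low-frequency structure (regions,
stain, signal) but draw their high-frequency noise independently per
level — a lower level is not the literal area-average of the base.
Coordinate geometry across levels is exact and tested; renders are
never downsampled from a materialised giant base raster, which would
cost hundreds of megabytes per slide.

*What passing on this generator does and does not show.* The planted
signal is a stain/texture shift — detectable by a small CNN, honest
about weak supervision (patient-level labels, multi-slide patients,
uninformative peri-tumor), and calibrated so the task is learnable
but not trivial at patch level. It does not emulate nuclear
morphology, stain variation families, scanner artifacts, or the
histologic features a pathologist would name; success here validates
the *pipeline machinery*, not clinical performance.

# Clinical simulators

Three tissue-limitation scenarios run on top of a scored cohort:

- **Single WSI**: one slide drawn per patient; the patient score is
  that slide's score.
- **k WSIs**: for each k, 100 iteration rounds (the published
  protocol) of sampling k slides per patient without replacement,
  reporting mean ± sd AUC.
- **Needle biopsies**: 1–3 cores per patient, each a contiguous strip
  of tumor patches placed at 10x and mapped to the 5x/20x patches of
  the same physical footprint, so one physical core feeds all three
  magnifications; bags are then drawn only from strip patches and the
  standard scoring path runs unchanged (tissue reduction changes the
  patch pool, never the formula). Placement retries 20 seeded anchors
  per length, shrinks the strip when the requested length cannot be
  placed, and flags the patient rather than silently dropping them
  when nothing fits. The default strip length is 3 patches at 10x —
  scaled to the synthetic slide geometry; `physical_area`
  bookkeeping (0.26 mm² per patch at 1 µm/px) is reported so users of
  real scanners can set a clinically realistic length (an 18-gauge
  core is on the order of 1 x 15 mm). The 3-core-vs-1-core benchmark
  runs on a dedicated cohort of single-slide patients with
  8192 x 8192 px slides, the smallest geometry in which three
  disjoint cores fit comfortably at 10x, with 30 simulation rounds —
  the band in the acceptance check scales with the measured sd, so
  the round count trades only precision, not validity.

# Interpretability

Per-patch attention scores (member-averaged, still summing to one per
slide) render as grid-aligned heatmaps; cohort-wide, the top and
bottom 4000 attention-ranked patches are extracted (full-sort
semantics, deterministic tie-breaks, flagged when the cohort is
smaller) and clustered on backbone features. Ranking uses the raw
attention weight by default; `rank_by = "weighted"` switches to
attention × bag score, since the literature leaves the choice open.
Clustering is k-means with 8 clusters by default behind a generic
interface — the labelling rule, not the cluster algorithm, is the
substantive part: a cluster whose members originate to strictly more
than 60% from positive patients is positive-related, strictly more
than 60% negative-origin is negative-related, and exactly 60% stays
unassigned. The 2-D display embedding is PCA; it is display-only.
Class-activation maps take the gradient of the positive-class logit
of a patch evaluated as a singleton bag at the last convolutional
layer; with global average pooling this reduces to the rectified
head-weighted sum of the final feature maps, normalised by its
maximum and upsampled bilinearly to 512 x 512.

# Evaluation

AUC is the tie-aware Mann–Whitney pair statistic; its variance,
confidence interval (normal approximation — the reference reports
CIs without naming a method, so DeLong-normal is declared) and the
two-sided test comparing two AUCs use DeLong's structural
components, in paired (shared subjects, joint covariance) and
unpaired forms. Swapping the models negates z and preserves p;
identical scores give p = 1 exactly. `best_accuracy_cutoff()` scans
the lowest score, midpoints of adjacent unique scores, and one point
above the maximum, maximising accuracy with ties to the lowest
cutoff; `confusion_metrics()` applies the ≥ convention. The unit
tests hold these against brute-force pair counting (exact to 1e-12),
a 2000-replicate bootstrap of the variance, a 500-simulation null
calibration of the test, and pROC as an independent implementation.

# Acceptance-check design notes

Two Monte-Carlo choices in the acceptance suite are worth recording.

*The permutation null.* With a strong one-dimensional planted signal,
a model trained on permuted labels does not score near chance against
the *true* labels: it collapses onto ± the texture direction, the
sign set by the permutation's accidental correlation with truth, so
the true-label AUC is bimodal near 0 and 1. Worse, evaluating against
a single global permutation is biased below 0.5 on the test set,
because a fixed label total couples the training-pool and test-set
halves of the permutation. The null here therefore permutes labels
*within each split group* (training pool and test set independently —
`permute_labels(within = split)`): the test-set permutation is then
exchangeable given the scores, the AUC against the permuted labels is
exactly centred on 0.5 for a leak-free pipeline, and a pipeline that
leaked manifest labels into scoring would still be caught. The
reported null is the mean over 12 replicates trained on the
single-magnification (5x) path with 12 epochs, giving a Monte-Carlo
standard error near 0.04 against the ±0.1 acceptance band.

*The tissue ablation.* Tumor-only and peri-tumor-only models are
compared at 20x (the magnification with the largest patch pool) over
the full cohort: both arms share training patients, so any
memorisation capacity inflates both, while only the tumor arm has
signal to use — the contrast isolates the information content of the
tissue category with the largest available patient count.

*Problem sizes.* The default suite trains the full three-magnification
classifier once on the 60-patient cohort, the ablation and null
models on single magnifications, the biopsy benchmark on a 36-patient
single-slide cohort, and the attention-localisation check (signal
confined to 25% of the tumor) on a 40-patient 10x-only cohort; these
sizes are the package's declared study conditions, chosen so every
claim is backed by a trained model rather than a stub.

# Degenerate inputs and numerical conventions

Scores are reported at full precision and rounded only for display.
Softmax attention subtracts the max before exponentiation; BCE clamps
probabilities at 1e-7; max-pool ties break in fixed tap order;
k-means seeds and all other randomness derive from a single run seed
through stable hashing (`mix_seed()`), so any stage can be reproduced
in isolation. Empty tissue selections, single-class label vectors,
incomplete ensembles, missing pyramid levels, unplaceable biopsy
cores and over-long splits all raise typed, message-bearing errors
rather than propagating NA — the tests exercise each path.

# Known limitations

- The slide readers load whole pyramid levels; they target the
  desk-scale synthetic slides and small TIFF exports, not gigapixel
  virtual-slide streaming.
- The tiny CNN backbone is not a pathology foundation model; absolute
  AUCs on real slides would hinge on substituting a stronger feature
  extractor behind the same contract.
- The generator's signal is intensity/texture-based; methods that
  only detect morphological arrangement would not be validated by it.
- Checkpoint selection assumes the fine-tune loss eventually rises;
  on very easy tasks it may never, in which case all epochs are
  eligible (by design, flagged in the ensemble summary).
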