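---
title: "Certainty-weighted wound segmentation: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certainty-weighted wound segmentation: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundseg)
```

## The problem

Forensic photographs of injured persons show skin wounds of several
morphological types — abrasions, subcutaneous hematomas, dermatorrhagia,
cuts, contused-lacerated wounds, stab wounds, thermal injuries — that a
pathologist must locate, delineate and classify. Semantic segmentation
automates this: every pixel is assigned to background or to one of the
seven wound classes. Three properties make this dataset regime unusual
and drive every design decision in this package:

1. **Extreme class imbalance.** Even the dominant wound class covers only
   about 1% of all pixels, all wounds together about 2%. A model that
   predicts "background" everywhere is 98% pixel-accurate and useless.
2. **Fuzzy boundaries.** Hematomas in particular have ill-defined
   borders; different annotators would draw different polygons.
3. **Label noise with known structure.** Annotators record how certain
   they are of each region's class ("not certain" / "quite certain" /
   "very certain"), and that certainty is informative.

## The loss

The core training loss is a certainty- and class-weighted binary
cross-entropy over the per-pixel softmax output $p_{ic}$ (pixel $i$,
channel $c$), with one-hot ground truth $g_{ic}$, pixel count $N$ and
$C$ channels:

$$
\mathrm{BCE} = -\frac{1}{C}\sum_{c}\left[
 \frac{w_c}{N}\sum_{i=1}^{N} m_i\, g_{ic} \log(p_{ic}+\epsilon)
 + \frac{1}{N}\sum_{i=1}^{N} m_i\,(1-g_{ic}) \log(1-p_{ic}+\epsilon)
\right]
$$

* $w_c = 1/(100 f_c)$ (or its square root) counteracts the class
  imbalance: $f_c$ is the pixelwise label frequency of class $c$,
  computed on the training split only, so the dominant class gets weight
  about 1 and rare classes more. A class absent from a split is capped
  at the weight a single pixel would produce.
* Only the first (false-negative) term carries $w_c$: missing wound
  pixels costs more than hallucinating them.
* $m_i \in \{0.5, 1.0, 1.5\}$ encodes the annotator's certainty for the
  region owning pixel $i$ (1.0 on background); switching
  `use_certainty_weights` off sets $m_i \equiv 1$.
* $\epsilon = 10^{-3}$ keeps gradients bounded near $p = 0$ and $p = 1$.

A note on the prefactor: the $-\tfrac{1}{C}\sum_c$ is applied to *both*
terms. The configuration option `prefactor_channels` chooses whether $C$
counts all softmax channels (default) or the wound channels only; this
is a constant scale that cannot change the optimisation direction, so
both variants are exposed and the default is the simpler one.

The focal Tversky loss is provided as the standard alternative:
per-class soft counts $TP_c, FN_c, FP_c$ form the Tversky index
$TI_c = (TP_c+s)/(TP_c+\alpha FN_c+\beta FP_c+s)$ and the loss is
$\sum_c (1-TI_c)^\gamma$ with $\alpha=0.7$, $\beta=0.3$, $\gamma=1.3$
(values reported to work well in the medical-segmentation literature;
this package deliberately does not re-tune them). The Tversky smoothing
$s$ defaults to 1.0 — a conventional value; the $\epsilon$ above is
documented only for the cross-entropy. `combo` mixes the two losses as
$\lambda\,\mathrm{BCE} + (1-\lambda)\,\mathrm{FTL}$ with free
$\lambda \in [0,1]$.

## Annotations and rasterization

Annotations follow the VGG Image Annotator (VIA) v2 dialect: per-image
records with polygon `shape_attributes` and `region_attributes`
carrying `class` and `likelihood`. Exact attribute naming in the wild
varies; this dialect is a documented assumption, and `write_via()` /
`parse_via()` round-trip it exactly.

Rasterization conventions (none of which are universal, so they are
fixed and tested here): coordinates are 0-based with x = column; pixel
$(r, c)$ belongs to a polygon iff its center $(c+0.5, r+0.5)$ is inside
under the even-odd rule; overlapping regions resolve by file order
(later wins) — the annotation protocol already assigns overlapping
wounds to the visually dominant class, so true overlaps are rare and any
deterministic rule suffices; self-intersecting polygons are rejected.
Three rare classes (semisharp force, puncture/gunshot, laceration) are
parsed and counted but rasterize to background, mirroring their post-hoc
removal from analysis. A missing likelihood defaults to the neutral
`quite_certain` with a warning.

For any convex polygon the rasterized pixel count differs from the
shoelace area by at most (perimeter + 4) pixels — the
boundary-discretization bound used throughout the tests, including to
cross-check the generator's independent point-in-polygon fill against
the scanline rasterizer.

## Evaluation

All metrics derive from a single pooled confusion matrix (rows = truth,
columns = prediction, background included), so they are invariant to how
pixels are distributed over images. *Mean pixel accuracy* is the macro
average of the row-normalised diagonal — per-class recall — and *mean
IoU* the macro average of $\mathrm{counts}_{cc}/(\mathrm{row}_c +
\mathrm{col}_c - \mathrm{counts}_{cc})$. Micro-averaged accuracy would
be ~98% for a background-only predictor given 2% wound area, which is
why the macro convention is the meaningful one here. Classes absent
from an evaluation set's ground truth are excluded from the macro means
rather than scored zero: rare classes routinely vanish from small
validation folds, and zero-scoring would punish the split, not the
model. Per-class IoU never exceeds per-class accuracy (the union is at
least the row sum); the tests verify this algebraic invariant on random
fixtures. In cross-validation, metrics are computed per fold and then
averaged arithmetically over folds.

## Training protocol

The protocol follows the reference regime: a held-out test set, the
remainder shuffled into k = 7 near-equal validation groups (sizes
differing by at most one; 1753 ids with 182 test images give folds of
225/1346 or 224/1347), batch size 8 with per-epoch reshuffling, Adam
(library-default $\beta_1 = 0.9$, $\beta_2 = 0.999$), and a learning
rate of $10^{-4}$ multiplied by 0.98 after every epoch over 100 epochs
($100$ multiplications: $10^{-4}\cdot 0.98^{100} \approx 1.3\times
10^{-5}$). Two checkpoints are kept per fold: the weights with the best
validation mean pixel accuracy, and the weights after the final epoch —
the two criteria trade pixel accuracy against IoU in opposite
directions, so both are always evaluated.

Images are resized to a square network input (bilinear for
photographs; nearest-neighbour for masks and certainty maps, which must
stay categorical). 512×512 is the full-scale input size; the desk-scale
default is 96×96. Stretching to square rather than padding is the
simpler convention and is applied consistently at train and test time.
Optional augmentation (flips, 90° rotations, mild brightness jitter) is
config-gated and off by default, applied identically to image, mask and
certainty map.

### The desk-scale reference models

Full-scale experiments in this problem domain use ImageNet-pretrained
encoders (SE-ResNeXt-50 and relatives) under U-Net or FPN decoders.
Reproducing those towers is out of scope; instead the package ships two
compact reference networks that preserve the architectural contrast:

* `unet_like` — a 3-level encoder-decoder with skip connections
  (widths 16/32/64 at the default base width);
* `fpn_like` — a 3-level bottom-up pathway with 1×1 lateral connections
  and a top-down merge.

Both end in an 8-channel 1×1 head with per-pixel softmax, stay well
under 500k parameters, and are trained by the package's own
forward/backward implementation (im2col convolutions, average pooling,
nearest-neighbour upsampling, Adam). Inputs are centered to $[-1, 1]$
inside the model. Weight initialisation is He-normal, seeded.

One optimisation constant deliberately differs between scales. The
$10^{-4}$ initial rate belongs to the *fine-tuning* regime: with
pretrained encoders, features only need small adjustments. Training the
reference networks from random initialisation is a different regime —
with Adam, each parameter moves at most about (learning rate) ×
(number of steps), so at $10^{-4}$ and the desk-scale step budget
(30 epochs × ~25 batches) no from-scratch model, however small, can
traverse the distance from a random initialisation to a useful solution.
The package therefore documents $3\times10^{-3}$ as the desk-scale
from-scratch rate (used by the end-to-end tests and the examples
below), while `train_config()` keeps $10^{-4}$ as the default protocol
constant. The decay factor, batch size, optimiser and checkpointing are
identical in both regimes.

## The synthetic-data generator

The real photographs are private, so the pipeline is exercised on a
seeded generator that emulates the *statistical* structure the method is
sensitive to — not photorealism:

* per-class target area fractions (defaults: dominant class 0.010,
  seven classes totalling 0.020) and a strongly skewed per-class
  region-count mixture, reproducing both kinds of imbalance;
* one geometry/appearance template per class (thin strip for cuts,
  small dark ellipse for stabs, diffuse soft-edged blob for hematomas,
  speckled patches for abrasions and contused wounds, dotted patch for
  dermatorrhagia, rimmed patch for thermal injuries), each rendered as a
  star-shaped random polygon scaled to its exact target area and
  composited with a soft (Gaussian-blurred) boundary;
* distractors: tattoo-like ink curves and blood-like background stains
  that are *not* annotated — they belong to the background class and
  exist to make false positives possible — plus whole-image blur and
  exposure jitter;
* per-region certainty labels whose distribution is biased toward
  `not_certain` (probability 0.7) when the rendered contrast is low,
  emulating that hard-to-see wounds are the uncertainly labelled ones.

Region counts are allocated deterministically per dataset
(`round(n_images × expected count)` regions per class, assigned to
images by seeded sampling) rather than drawn independently per image;
this keeps realized area fractions within a few percent of their
targets, which the manifest records and the tests check (±20% at 100
images). The emitted polygon annotations delineate the pre-blur
footprint (the 0.5 level of the rendered alpha), and reference masks are
produced by the generator's own even-odd fill — an implementation
independent of the package's scanline rasterizer, so the two can be
cross-checked.

What the generator does **not** emulate: real skin texture and lighting,
anatomical context, perspective, wound co-occurrence patterns, treated
wounds, 3D imaging. Passing end-to-end tests on synthetic data therefore
demonstrates that the pipeline's mechanics are correct and that the loss
can drive learning under realistic imbalance — not that any particular
accuracy transfers to real forensic photographs.

Class appearances were chosen (once) to be linearly separable in RGB —
a pixelwise multinomial probe attains at least 80% per-class recall on
sampled wound pixels — because a dataset a small reference model cannot
learn would make every training test vacuous.

## Problem sizes used in the tests

The test suite runs entirely on generated data: unit fixtures up to
8×8 pixels for the loss algebra; 16–100 images at 48–96 px for module
and distribution checks; one full end-to-end run (200 images at 96×96,
30 epochs, ~10 minutes on one CPU core) for the learning sanity check;
and three seeded pairs of smaller runs (60 images, 10 epochs) for the
qualitative direction checks — the final-epoch checkpoint tending to a
higher IoU than the best-validation-accuracy checkpoint, and square-root
class weights tending to fewer false-positive wound pixels. The latter
two mirror reported tendencies and are advisory: directions are
computed and reported, not hard-failed, since at desk scale they are
genuinely stochastic.

## Numerical and degenerate-input choices

* Softmax ties at prediction time break toward the lowest class index,
  so an exactly uniform output yields background.
* `class_frequencies` over an all-background split flags wound classes
  as absent; `class_weights` caps their weight at the one-pixel value
  with a warning instead of dividing by zero.
* Polygons fully outside the image warn and contribute nothing;
  polygons with fewer than three distinct vertices are errors.
* A non-finite training loss aborts with the epoch, batch and learning
  rate in the message.
* Certainty maps persist as 8-bit level-index PNGs (codes 1/2/3) with
  the code-to-weight mapping in the dataset sidecar.
* All randomness — generator, splits, initialisation, shuffling — is
  seeded; identical seeds reproduce datasets bit-for-bit and training
  runs exactly.

## A worked desk-scale example

```{r example, eval = FALSE}
library(woundseg)

cfg <- synth_config(n_images = 60, seed = 7)
ds <- generate_dataset(cfg, "wounds60")
stats_for_dataset("wounds60")

cv <- run_experiment(
  list(
    synth = list(n_images = 60, seed = 7),
    model = list(family = "unet_like"),
    loss  = list(family = "weighted_bce", use_certainty_weights = TRUE),
    train = list(epochs = 15, lr0 = 3e-3, seed = 1),
    split = list(n_test = 10, k = 3, seed = 1)
  ),
  run_dir = "run60"
)
glance(cv)
autoplot(cv$pooled_confusion$best_val_mpa)
```

## Known limitations

* The reference networks are far smaller than the pretrained encoders
  used at full scale; absolute metric levels on synthetic data say
  nothing about levels on real forensic photographs.
* The exact VIA attribute names of any given annotation project may
  differ from the documented dialect and then need renaming on import.
* Whether a connected injured area is one region or several is an
  annotation-time decision; the rasterizer is agnostic.
* The combination weight $\lambda$ of the mixed loss and the channel
  count of the BCE prefactor are exposed but have no canonical values.
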