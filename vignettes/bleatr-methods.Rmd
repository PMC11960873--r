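---
title: "Classifying and explaining goat vocalizations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and explaining goat vocalizations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bleatr)
```

## The problem

Goats vocalize differently depending on the situation they are in: heat,
feed distribution, parturition, injury or death events, social isolation,
reunion with or separation from their kids, and the presence of unknown
visitors. An acoustic monitoring system that recognizes these contexts from
farm recordings can support animal-welfare work, but it is only usable by
animal scientists if its decisions can be inspected: which time-frequency
content drove a prediction, which recordings the model considers similar,
and how two vocalizations differ in the model's eyes.

`bleatr` implements that full loop: a log-Mel frontend, tempo/pitch
augmentation, a VGG-style convolutional classifier trained under stratified
cross-validation, conditional relevance propagation for explanations, an
interactive question-answering layer with sonification, and a seeded
synthetic call generator so every stage can be exercised and tested without
access to a field corpus.

## Frontend

Audio is ingested as mono (channel-averaged), polyphase-resampled to
22050 Hz, and peak-rescaled only if it exceeds full scale. Clips shorter
than 2 s are zero-padded at the tail to exactly 2 s; longer clips are passed
through unchanged and left to the sliding window, which keeps all signal at
the cost of a variable segment count — trailing (rather than centered)
padding keeps call onsets where they were recorded.

Each clip is split into 1-s analysis segments with 50% overlap. Windows are
tiled at 11025-sample hops; if the full windows do not cover the clip's
tail, one final zero-padded window is added.

The spectrogram of a segment is the magnitude STFT (1024-sample periodic
Hann window, 512-sample hop, frames centered on multiples of the hop),
squared to power, pooled by a 128-band triangular mel filterbank spanning
0 Hz to Nyquist, and compressed as `log(P + eps)` with `eps = 1e-10`.
Centered framing gives `1 + floor(22050/512) = 44` frames, so one segment
is always a 128 x 44 matrix; digital silence maps to the uniform floor
`log(1e-10)`. The mel scale variant is configurable (`"slaney"` default,
`"htk"` available) because the choice is immaterial to the pipeline's
contracts but changes band center frequencies slightly.

## Augmentation

Training segments are expanded on a 3 x 5 grid: tempo rates
{0.8, 1.0, 1.2} by pitch shifts of -2 … +2 semitones, 15 variants including
the identity pair. Time stretching is a classic phase vocoder (magnitude
interpolation with per-bin phase accumulation); the stretched result is
refitted to exactly 1 s (tail trim or zero-pad) before pitch shifting, so
feature shapes stay constant. Pitch shifting by `s` semitones is a
phase-vocoder stretch by `2^(-s/12)` followed by rational resampling back
to the original length, scaling all frequencies by `2^(s/12)`. Identity
cells short-circuit to the unmodified segment. Augmented variants inherit
their parent's label and source id, and evaluation always runs on original
(non-augmented) clips only — the training code raises an error if an
augmented clip reaches a test set.

## Architecture

The classifier is a VGG-style stack: four blocks of two same-padded 3 x 3
convolutions with ReLU followed by 2 x 2 / stride-2 max pooling, with
nominal filter counts 64, 64, 128, 128, 256, 256, 512, 512. The pooled
8 x 2 map is flattened and passed through two 4096-unit fully connected
ReLU layers, dropout (rate 0.5), and an 8-way softmax. Kernel size, pool
geometry, same padding, and the dropout rate are the conventional choices
for this family; odd pooled dimensions floor-divide (44 → 22 → 11 → 5 → 2).

A width multiplier scales convolutional filters and dense units jointly so
that the same topology can run at desk scale: width 0.125 gives filters
8, 16, 32, 64 and 512-unit dense layers (about 0.87 M parameters instead of
~150 M). Weights are He-initialized from a seeded stream; the same
`(spec, seed)` pair is bit-reproducible.

## Training protocol

The reference protocol is Adam with learning rate 1e-4, batch size 12, at
most 14 epochs with early stopping, and stratified 5-fold cross-validation.
Folds are assigned at the source-recording level: sources are shuffled
within each class and dealt round-robin, so per-fold class counts are
within one source of proportionality, and a clip's segments and augmented
variants can never straddle a fold boundary. Early stopping monitors
validation loss on a stratified 10% split of the training sources
(patience 3, best parameters restored). A clip-level prediction is the
argmax of the arithmetic mean of its segments' softmax rows; reported
confusion matrices are row-normalized, and the headline number is the mean
of the per-class rates averaged over folds.

### The desk-scale profile

`synthetic_benchmark()` runs the standard end-to-end experiment used by the
package's own test suite: 40 synthetic clips per class, width 0.125,
identity augmentation grid, learning rate 1e-3, at most 6 epochs with
patience 2, stratified 5-fold cross-validation, seed 7. The shorter, hotter
schedule matches the smaller model and corpus (about 2000 optimizer steps
rather than tens of thousands), and the identity grid keeps the experiment
proportionate — the 15-variant grid's correctness is contracted separately
at the unit level, and fold hygiene of augmented training sets is tested
with the full grid. This profile reaches a mean per-class recall above 0.99
on the bundled generator's default conditions.

## Relevance propagation

Explanations use backward relevance decomposition with the standard
composite rule set for VGG-like networks: the alpha1/beta0 (z+) rule for
convolutions, the epsilon rule (`eps = 1e-6`) for fully connected layers,
winner-take-all routing through max pooling (relevance follows the pooling
switches), and identity through flatten/dropout. Relevance is seeded at the
output layer with the target class's *pre-softmax* score. Two deliberate
numerical choices:

* **Biases are excluded from rule denominators.** Total relevance is then
  conserved exactly on zero-bias networks, which makes conservation a sharp
  test rather than an approximate one; on trained networks the small bias
  leak is accepted, as is standard.
* **Signed inputs are handled explicitly** in the z+ rule via the
  `(x+, w+) + (x-, w-)` decomposition, because log-Mel inputs are negative
  almost everywhere (the log floor is about -23).

*Conditions* restrict relevance flow: a condition set maps layer names to
allowed channel subsets, and relevance arriving at a conditioned layer's
output is zeroed outside the subset before propagation continues. Every
rule is linear in the incoming relevance, so the singleton-channel
conditional heatmaps at any layer sum exactly to the unconditional heatmap
— the defining decomposition, verified to 1e-6 relative in the tests.

Channel rankings score each channel by the sum of its relevance over all
spatial positions, descending, ties broken by ascending channel index.
Sample reports render the top-k (default 6) conditional heatmaps per
analyzed layer. "Layers" always means the convolutional and dense layers;
pooling layers have no independent parameters or channels of their own.

### Class-wise average heatmaps

For each class, the `n` most central spectrograms are selected by Euclidean
distance to the class mean (k-means with k = 1 reduces to the mean; ties
keep corpus order), and for each of those samples the top `g` channels per
analyzed layer contribute one conditional heatmap each. The arithmetic mean
of all collected maps is the class heatmap. Two counts are recorded: the
actual contributor count `n * g * n_layers`, and a nominal per-class budget
`|D| * n * g` (with `|D| = 8` the dictionary size). The nominal budget
multiplies by the dictionary cardinality even though a single class's
average cannot draw maps from other classes, so the two numbers differ by
design; both are reported rather than silently reconciling them.

## The interaction layer

Four question types close the loop for a human expert:

1. **Influence**: the relevance map for the predicted class is computed on
   the segment that drives the clip-level decision (highest probability for
   the predicted class), thresholded at the p-th percentile (default 90) of
   its positive values, reported as time extents (frame centers, seconds)
   and frequency extents (mel band centers, Hz), and sonified.
2. **Similar** and 3. **Dissimilar**: cosine distances in embedding space
   (the second fully connected layer's post-ReLU activation, averaged over
   a clip's segments; configurable). Post-ReLU embeddings are non-negative,
   so distances live in [0, 1]; similar/dissimilar are the two orderings of
   the same distance vector, and the distances themselves are reported.
4. **Difference**: each clip's heatmap for its own predicted class (the
   alternative — using one clip's class for both — is a one-line change),
   min-max normalized to [0, 1] so recordings of different energy are
   comparable, subtracted; cells above the p-th percentile of the absolute
   difference are masked and sonified for both clips.

Sonification lifts a mel-plane mask to the linear STFT plane with the
pseudo-inverse of the mel filterbank, normalized by the lifted all-ones
mask so that a fully transparent mask reproduces the input (round-trip
correlation above 0.95), clipped to [0, 1], multiplied into the complex
STFT (original phases preserved), and inverted by weighted overlap-add.
An all-zero mask yields digital silence, and masking never adds energy.

## The synthetic generator

Each of the 8 classes is a parametric harmonic call: a fundamental sampled
from a class-specific range, linear frequency modulation, sinusoidal
amplitude modulation under a raised-cosine onset/offset envelope, a
class-specific duration range, and a *discriminative frequency band* —
partials outside it are attenuated by 40 dB — embedded at a random onset in
a 2-s window over a pink-noise floor. Defaults give the classes
pairwise-disjoint bands spread over 140 Hz–9 kHz, durations from 0.2 to
1.7 s, and an SNR of 25 dB (a relatively clean pre-segmented clip), chosen
so that every class's in-band energy exceeds its out-of-band energy by at
least 6 dB even for the shortest calls, which integrate proportionally more
noise over the 1-s analysis window. Randomized onsets force the classifier
to rely on pooling's translation tolerance rather than absolute position.

What the generator does *not* emulate: real goat vocal-tract acoustics,
overlapping calls, farm soundscapes (machinery, other species),
channel/microphone variation, or label noise. Passing tests on this corpus
demonstrate that the pipeline's machinery is correct and that the
explanation methods recover planted structure; they say nothing about
classification rates on field recordings.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: 40 clips per class (320
clips, 960 segments), width 0.125, 5 folds, seed 7 for the cross-validation
experiment; 20 probe calls per class for explanation localization; 100
clips for retrieval checks; and toy dense networks of at most 3 layers and
16 units for conservation checks (1e-4 relative). Channel decomposition is
checked at 1e-6 relative, softmax row sums at 1e-6, and stretch/shift
oracles at a few Hz via FFT peak picking. These sizes are the package's
standard desk-scale experiment; scaling the corpus or width up is a
configuration change, not a code change.

## Known limitations

* No denoising, voice-activity detection, or call detection: inputs are
  assumed to be pre-segmented labeled clips.
* No transfer-learning baselines; the package implements the custom
  architecture only.
* The phase vocoder introduces the usual transient smearing; the identity
  grid cell bypasses it, and resynthesis quality is contracted only through
  frequency-ratio and correlation oracles.
* Training is CPU-bound R/C++ and intended for desk-scale widths; the
  full-width protocol is expressed by the same code but is a long-running
  job.
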