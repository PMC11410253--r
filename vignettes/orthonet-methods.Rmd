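---
title: "orthonet: models, probes and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthonet: models, probes and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model, the
probing procedures, the tunable parameters and the places where the design
was genuinely open, together with what the synthetic-data validation does
and does not establish.

## The model

`orthonet` studies how a ventral-stream-style convolutional network develops
an invariant code for written words. The architecture (CORnet-Z family) has
four blocks named after cortical areas — V1, V2, V4, IT — each a single
convolution followed by rectification and 3×3/stride-2 max-pooling. V1 uses
a 7×7 kernel with stride 2; the other blocks use padded 3×3 kernels with
stride 1, so each block halves the spatial grid. A global average pool over
IT ("avgIT", no additional parameters, higher invariance) feeds a fully
connected readout. With the default widths (64, 128, 256, 512) and 224×224×3
inputs the block outputs are V1 64×56×56, V2 128×28×28, V4 256×14×14 and IT
512×7×7.

Training is plain stochastic gradient descent (momentum 0.9) on categorical
cross-entropy, with a step-decay learning rate: initial 0.01, multiplied by
0.1 every 10 epochs. (The schedule is sometimes described as "linear with a
step size of 10 and gamma 0.1", which conflates two scheduler families; we
implement the named default-gamma step scheduler, the only reading
consistent with a multiplicative gamma.) Literacy is modelled in two phases:
phase 1 trains on object categories only (the *illiterate* network); phase 2
extends the output layer — new columns initialized at zero mean, sd 1e-3, so
pre-existing logits are untouched at step 0 — and retrains the whole network
jointly on objects and words (the *literate* network). The illiterate
control continues object-only training for the same number of epochs, so the
two networks differ in experience, not duration.

Inputs are normalized by fixed constants (mean 0.92, sd 0.25, the statistics
of the synthetic stimuli: dark ink on a light background) before the first
convolution. The engine (im2col + GEMM convolution, max-pooling, and their
gradients) is compiled C++ via RcppArmadillo; gradients are verified against
finite differences in the test suite.

## Stimuli

Words are rendered as dark glyphs on a light square canvas. Glyphs come from
procedural 5×7 bitmap fonts defined in code and scaled by nearest-neighbour
resampling; five deterministic variants (sans, bold, slant, serif,
backslant) play the role of a font family, with sans/bold reserved for
training sets and the other three for test sets. This keeps every image a
pure, bit-reproducible function of its arguments with no binary font assets;
the price is that the "fonts" differ less richly than real typefaces, and
lower case is rendered as reduced-height upper-case shapes.

Dataset variants sample size (30–70 pt), horizontal/vertical offset (±50 and
±30 px at the 224 canvas; proportionally scaled elsewhere) and case. The
point-to-pixel scale is chosen so that words fit the canvas at moderate
sizes, but an 8-letter word at 70 pt cannot fit any 224-px canvas with a
±50 px offset under any real font metric — the printed ranges are mutually
inconsistent at the extremes. We therefore sample each variant uniformly
from the *admissible* part of the configured ranges: the largest size at
which the word fits is found first, then the offset range is truncated to
keep all ink on canvas. Every sampled value lies inside the configured
ranges, and rendering errors (rather than clips) if asked to draw outside
the canvas.

Probe stimuli use an 8-slot frame of equal-width slots centred on the
canvas; a word of length L occupies L contiguous slots, and the `-`
character is a truly empty slot (no ink). This slot convention is our
construction — the probe schematics do not specify inter-letter spacing —
and it is what makes "retinotopic position" well defined across probe rows.
The factorial design crosses 5 absolute word positions (rows) with the 4
ordinal positions of a single preferred letter inside a string of
unpreferred letters (`oxxx` … `xxxo`); the spaced design reduces the string
to 3 letters separated by single blanks (`x-o-x`), giving a 4×3 matrix.

The category localizer contrasts words with faces, houses, bodies and
tools. These categories are procedural (textured blob faces, rectilinear
house composites, articulated body silhouettes, elongated handled tool
shapes): the localizer needs non-word contrast categories with comparable
image statistics, not photographs. Four filler shape classes (blobs,
stripes, rings, wedges) enrich the phase-1 object task to eight classes.

## The probing suite

**Word-selective units.** A unit is word selective when its mean response to
word stimuli exceeds the mean response to *every* non-word category by
`k_sd = 3` of that category's across-stimulus standard deviation — the
strictest reading of the localizer criterion, matching fMRI practice. The sd
is per category, not pooled; responses are raw post-rectification
activations. The criterion is invariant to adding a constant to a unit's
responses and equivariant under positive scaling.

**Letter tuning.** Each selective unit is probed with every letter at each
of the 8 slots (26×8 = 208 stimuli); the max across slots per letter gives
its preferred and least-preferred letters, which then parameterize its
factorial probe.

**Encoding models.** Responses to a word list are regressed on a binary
words × 208 letter-by-slot matrix, Y = Xb, by lasso with the penalty chosen
by internal 5-fold cross-validation (`glmnet::cv.glmnet`, folds seeded and
shared across schemes). Three schemes assign a word's letters to slots:
left-aligned (slots 1..L), word-centred (offset ⌊(8−L)/2⌋), and edge-aligned
(the first ⌈L/2⌉ letters indexed from slot 1, the rest ending at slot 8; the
odd-length split is our convention — the scheme is defined by a 4-letter
example — and is configurable). All schemes have identical feature counts,
so fits are comparable. Fit quality `cv_r` is the Pearson correlation
between *out-of-fold* predictions at the CV-optimal penalty and the observed
responses; in-sample correlation would favour no scheme but overstate all of
them. Constant responses are flagged degenerate with `cv_r = 0`. Scheme
winners within `tie_tol = 0.05` of the runner-up are flagged as ties; the
value separates genuinely tied cases (a position-invariant unit fits all
three schemes within ~0.03) from genuine wins (planted edge-aligned units
beat the alternatives by ≥ 0.15).

**Position tuning.** Coefficients are reshaped to 26×8, averaged over
letters, normalized by each unit's own maximum, grouped by peak slot, and
averaged within group. On populations with planted sharp edge tuning and
broad middle tuning this reproduces the sharper-at-the-edges pattern.

**Response profiles.** The 5×4 factorial response matrix is binarized at
30% of its range above the minimum (`min + 0.3·(max − min)`; the wording
"30% of the difference between maximum and minimum" supports this over
`0.3·max`). Units whose maximum response is below the exclusion threshold
(default 5, in the activation units of the full-scale network) are excluded,
as are constant matrices. Binarization is invariant under positive affine
rescaling, hence so is the categorization.

The categorizer counts consecutive active cells along rows, columns,
diagonals and reverse diagonals. Run counting itself is standard; the
decision thresholds and tie-breaks are not canonical, so ours are declared
explicitly: a direction claims the pattern when (a) its
longest run has at least `min_run = 3` cells, (b) at most `max_stray = 1`
active cells fall outside runs of that length — this tolerates the banded
diagonals of broadly tuned retinotopic units while rejecting scattered
patterns such as checkerboards — and (c) the active cells do not occupy
every line of the direction (a fully covered matrix, e.g. a
position-invariant letter detector, carries no positional information).
Priority on ties is column (ordinal) > diagonal (retinotopic) > row (word
position); everything else is mixed. Ordinal claims are column-structured
runs of ≥ 3 consecutive rows: requiring a *full* column would deny ordinal
coding to mid-layer edge units whose retinotopic windows cover only part of
the rows. One consequence of the run-length requirement is conservatism at
matrix corners: a sharply tuned retinotopic unit preferring slot 1 or 8
activates at most 2 cells and is classified mixed. The implementation
(line-scan run statistics in C++, decision rule in R) is checked against an
independent per-cell enumeration with its own C++ decision rule on all 2^20
binary 5×4 matrices.

**Spaced reclassification.** Units categorized ordinal on the factorial
design are re-probed with the spaced design, where every letter is flanked
by blanks. A genuine ordinal unit keeps responding in one fixed column; a
space-bigram unit (tuned to its letter adjacent to a blank inside a
retinotopic window) now responds wherever the letter's canvas slot falls in
its window — support that drifts across columns at a constant slot. The
rule: single-column support (≥ 2 cells) → ordinal; support spanning ≥ 2
columns with preferred-letter slots within `slot_tol = 3` of each other (a
mid-layer window width) → space bigram; anything else → other. Units not
ordinal on the factorial design return "other" by definition of the probe.

**Connectivity.** For a target unit, each input channel's filter is
collapsed by *summing* its 3×3 kernel — rectified inputs are non-negative,
so negative weights only dampen and a norm would hide the sign — and
multiplied by the channel's drive: the maximum response over the target's 20
probe stimuli among word-selective input units inside the target's effective
receptive field (5×5 on V4 for an IT unit). Channels with no word-selective
unit in the field get drive 0 and a flag. The top-k products per sign
(default 2) are reported as excitatory/inhibitory. The V4→V2 analysis runs
through the identical code path. First-layer kernels are characterized by
the radial frequency of their 2-D Fourier amplitude peak (averaged over
input channels) and median-split into low/high classes; the median split is
our choice of cut.

**Dissimilarity.** d = 1 − r with r the Pearson correlation between two
stimuli's vectorized layer activations (all units of the layer, not only
selective ones, matching the vectorize-the-layer procedure). Mean pairwise
dissimilarity over a 49-bigram set gives C(49,2) = 1176 pairs. Network
comparisons use a paired two-sided t-test over matched pair values, with an
optional seeded sign-flip permutation test alongside; zero-variance stimulus vectors
are dropped with a warning.

## Synthetic units

Synthetic units respond to *symbolic* stimulus descriptions (which glyph is
in which slot), never to pixels, so the whole analysis chain can be
validated without a trained network and independently of training noise.
Kinds: retinotopic (gaussian tuning around a canvas slot), ordinal from word
start or end (indicator, or gaussian in ordinal distance), space bigram left
/ right (letter flanked by a blank inside a slot window), letter-invariant,
word-position, and weighted mixtures. Default gain is 10 — safely above the
exclusion threshold of 5 — and noise is additive gaussian truncated at 0 to
mimic rectified activations. Parameter-recovery tests plant 200 units across
kinds (mid-frame positions, windows 3–6, so the probe designs cover their
tuning) and require 100% label recovery noiseless and ≥ 95% at noise sd =
10% of gain.

## The desk-scale literacy experiment

Full-scale training (ImageNet-sized object sets, 224-px canvases, 50 + 30
epochs) is out of desk scope. The scaled profile (`scaled_profile()`) is the
package's chosen study condition for the emergence experiment, fixed once:

- canvas 64×64, stimulus ranges scaled proportionally; probe letters at
  50 pt;
- network widths (8, 16, 32, 64);
- 20 frequent French words of 3–8 letters, 100 training / 20 test variants
  per word; 8 procedural object classes with 150/20 images each;
- 6 phase-1 epochs, 8 phase-2 epochs, batch 32, learning rate 0.01,
  momentum 0.9;
- localizer with 200 word and 50 per-category images; 49-bigram
  dissimilarity set;
- profile exclusion threshold 0.5 (this network's activations are roughly
  an order of magnitude smaller than the full-scale network's, for which
  the default of 5 is calibrated);
- at most 60 profiled units per layer.

These sizes were fixed from pilot runs of the training harness (the
experiment takes a few minutes per seed on one CPU). At this scale a
literate network reaches roughly 0.35–0.50 top-1 accuracy on held-out-font
word variants (chance 0.05) while object accuracy stays within a 0.2 band
of the illiterate control's; the desk-scale acceptance bound is ≥ 0.15.
Generalization is limited mainly by the two-training-font regime at tiny
glyph sizes, not by word identity learning (training-font accuracy is much
higher).

What the desk-scale experiment *does* show, consistently across seeds:
more word-selective avgIT units in the literate network than its illiterate
control; higher mean bigram dissimilarity from V4 onward (paired t,
p < 5×10⁻⁴); and the existence of ordinal-category units in late layers
(pooled across seeds — at this scale individual seeds fluctuate, and layer
IT has only a 2×2 grid). What it does *not* show: the unit proportions
characteristic of full-scale training,
behaviour on photographic object categories or real typefaces, or any
claim about biological tissue. The synthetic-unit validations establish
that the *analyses* are correct; the scaled experiment establishes that the
*phenomena* emerge qualitatively under the package's training conditions.

## Numerical and interface choices

- Indices are 1-based everywhere, following R convention, including unit
  addresses (`unit_index`/`unit_address` document the flat ordering).
- Weight initialization is He-style normal (sd √(2/fan-in)); minibatch
  order, initialization and stimulus sampling all draw from private seeded
  RNG streams, so every result is reproducible from a single seed and
  library code never perturbs the caller's RNG state.
- Max-pooling treats padding as absent (padded cells never win), matching
  the usual −∞-padding semantics; pooling gradients flow to argmax cells
  only.
- The lasso path uses 50 lambdas; `cv_r` of a noiseless single-feature
  response reaches 1 only to within ~1e-6–1e-5 because out-of-fold
  predictions mix per-fold solutions at coordinate-descent tolerance.
- `effective_receptive_field` composes exact interval inversions of each
  (kernel, stride, padding) op and clips at grid borders; it is tested
  against brute-force influence masks (delta inputs forwarded through
  ones-kernel convolutions and max-pooling), including corner units where
  clipping makes the box asymmetric.
- Degenerate cases are explicit: empty training sets, missing probe
  stimuli, unknown layers and fonts, zero-variance vectors and constant
  response matrices all raise or flag rather than silently proceeding.

## Known limitations

- Procedural bitmap fonts are a deliberate simplification; claims about
  font-invariance at desk scale concern these five variants only.
- The spaced-reclassification rule assumes the unit's window covers
  mid-frame slots; units tuned to extreme slots can return "other".
- The categorizer is conservative at matrix corners (see above).
- avgIT in the scaled profile has 64 units; selective-unit counts there are
  small integers and should be read as such.
- The experiment driver profiles V4, IT and avgIT; V1/V2 units at desk
  scale have receptive fields of only a few pixels and their factorial
  matrices are dominated by the exclusion rule.
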