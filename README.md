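# orthonet

Fluent readers recognize a word — and distinguish anagrams such as FORM and
FROM — invariantly over position, size, font and case. In the brain this is
attributed to the visual word form area (VWFA); in convolutional networks
trained to recognize written words, an analogous code emerges: a small set of
word-selective units whose responses encode *which letter* sits at *which
ordinal position*, counted from the word's left or right edge, rather than at
a fixed retinal location. `orthonet` is an R toolkit for producing and
dissecting such networks at desk scale: it generates synthetic word-image
datasets, trains a compact ventral-stream-style network in two phases
(objects only → objects + words), and probes how its units encode letters and
their positions.

The package is aimed at computational-neuroscience work on reading: testing
letter-position coding schemes, exploring how "space bigram" units (letter
next to a blank) bridge retinotopic and ordinal codes, and validating those
analyses with synthetic units of known tuning.

## What it implements

- **Stimulus generation** (`render_word`, `make_training_set`,
  `make_factorial_probe`, `make_spaced_probe`, `make_single_letter_grid`,
  `make_bigram_set`, `make_localizer_set`): dark-ink word images with
  procedural bitmap fonts (5 deterministic variants, disjoint train/test
  sets), variable size, offset and case; the factorial probe matrices that
  cross absolute word position with the ordinal position of a single
  preferred letter; and procedural face/house/body/tool categories for the
  localizer contrast.
- **Network and training** (`network_spec`, `build_network`, `train_cornet`,
  `extend_output`, `record_activations`, `effective_receptive_field`): a
  CORnet-Z-family architecture — blocks V1, V2, V4, IT, each convolution →
  rectification → max-pool, then a global average pool (avgIT) and a fully
  connected readout — trained by SGD on cross-entropy with a step-decay
  learning rate (×0.1 every 10 epochs from 0.01). The conv/pool forward and
  backward passes are compiled (RcppArmadillo, im2col + GEMM). Phase-2
  literacy training extends the output layer and retrains jointly on objects
  and words. Receptive fields are backprojected exactly through the
  intervening kernel/stride/padding geometry; with the default architecture
  an IT spatial unit sees a 5×5 window of the 14×14×256 V4 grid.
- **Dissection suite**:
  - `find_word_selective`: localizer contrast — a unit is word selective
    when its mean word response exceeds every category mean by 3 of that
    category's standard deviations;
  - `letter_tuning`: 26 letters × 8 slots responses, max over slots;
  - `build_design_matrix` / `fit_encoding` / `compare_schemes` /
    `position_tuning`: the linear encoding model **Y = Xb** (cross-validated
    lasso; X is a words × 208 binary letter-by-slot matrix) under
    left-aligned, word-centred and edge-aligned position schemes;
  - `classify_profile` / `categorize` / `spaced_reclassify`: binarization of
    the 5×4 factorial response matrix at 30% of its range (units with
    maximum below the exclusion threshold are dropped) and run-based
    categorization into ordinal / retinotopic / word-position / mixed, plus
    the spaced design that separates genuine ordinal coding from
    space-bigram coding;
  - `attribute` / `filter_weight_sums` / `channel_drive` /
    `v1_filter_spectrum`: cross-layer connectivity attribution (summed
    kernel weights × maximal word-selective drive within the receptive
    field) and spatial-frequency classification of first-layer filters;
  - `dissimilarity` / `mean_pairwise` / `compare_networks`: correlation
    distance d = 1 − r between activation patterns, mean pairwise
    dissimilarity over bigram sets, and literate-vs-illiterate comparisons.
- **Synthetic units** (`synthetic_unit`, `respond`, `generate_population`):
  planted retinotopic / ordinal / space-bigram / letter-invariant /
  word-position / mixed tuning defined on symbolic stimulus descriptions,
  with truncated gaussian noise — the ground truth against which every
  analysis stage is validated by parameter recovery.
- **The experiment driver** (`run_literacy_experiment`, `scaled_profile`):
  the full desk-scale pipeline — train an illiterate/literate pair, count
  selective units, compare bigram dissimilarity, categorize response
  profiles.

## Worked example

Probe a synthetic ordinal unit (tuned to the letter O at the first ordinal
position, noise sd = 1) with the factorial design, then with the spaced
design:

```r
library(orthonet)
probe <- make_factorial_probe("o", "x", render = FALSE)
matrix(probe$strings, 5, 4, byrow = TRUE)
#>      [,1]       [,2]       [,3]       [,4]
#> [1,] "oxxx----" "xoxx----" "xxox----" "xxxo----"
#> [2,] "-oxxx---" "-xoxx---" "-xxox---" "-xxxo---"
#> [3,] "--oxxx--" "--xoxx--" "--xxox--" "--xxxo--"
#> [4,] "---oxxx-" "---xoxx-" "---xxox-" "---xxxo-"
#> [5,] "----oxxx" "----xoxx" "----xxox" "----xxxo"

unit <- synthetic_unit("ordinal_start", "O", position_param = 1, noise_sd = 1)
cl <- classify_profile(respond(unit, probe, seed = 7), probe)
round(cl$raw, 1)
#>      [,1] [,2] [,3] [,4]
#> [1,] 12.3  0.0  0.0  0.0
#> [2,]  9.0  0.0  0.7  0.0
#> [3,] 10.2  2.2  0.4  2.7
#> [4,] 12.3  0.3  1.9  0.5
#> [5,]  9.1  0.0  0.0  1.0
cl$category      # "ordinal"   — column structure: fires at ordinal position 1
cl$preferred     # 1           — the preferred column

spaced <- make_spaced_probe("o", "x", render = FALSE)
sp <- classify_profile(respond(unit, spaced, seed = 7), spaced)
spaced_reclassify(cl$category, sp, spaced)
#> [1] "ordinal"   — still column-bound when letters are s p a c e d:
#>                   genuine ordinal coding, not a space-bigram unit
```

The response matrix is strongest down column 1 — the unit follows the
letter's ordinal position, not its canvas slot (which would produce a
diagonal). The encoding-model features and the architecture's receptive
fields behave as expected:

```r
X <- build_design_matrix("WORD", "edge_aligned")$X
colnames(X)[X[1, ] == 1]
#> [1] "w1" "o2" "r7" "d8"    # initial letters from the left edge,
                             # final letters from the right edge

model <- build_network(network_spec(224), n_out = 10)
effective_receptive_field(model, "IT", 4, 4, "V4")$side
#> [1] 5                      # one IT unit sees a 5x5 window of V4
```

`run_literacy_experiment(seed)` runs the full desk-scale study (a few
minutes on one CPU) and returns selective-unit counts, per-layer bigram
dissimilarity comparisons, and response-profile categories for a literate
network and its illiterate control.

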