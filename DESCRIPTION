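Package: orthonet
Title: Dissecting Letter-Position Codes in Word-Trained Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how convolutional networks trained on written
    words develop an invariant letter-by-ordinal-position code, mirroring the
    visual word form area. Provides a synthetic word-image generator with
    procedural fonts, a compact ventral-stream-style convolutional network
    (V1/V2/V4/IT blocks) with a two-phase illiterate-to-literate training
    harness, and a full probing suite: word-selective unit localization,
    letter-by-position encoding models under alternative position schemes,
    factorial response-profile categorization (retinotopic, word-position,
    ordinal, mixed), spaced-string probes for space-bigram coding, cross-layer
    connectivity attribution, V1 spatial-frequency characterization, and
    correlation-distance representational dissimilarity. A synthetic-unit
    generator with planted tuning validates every analysis stage by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: glmnet, stats, utils, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
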