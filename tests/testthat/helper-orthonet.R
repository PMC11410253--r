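# Shared test helpers: independent oracles and synthetic inputs.

# Brute-force influence mask: which positions of `to_layer`'s output grid can
# influence the given unit? Forward-propagates a delta through ones-kernel
# convolutions and max-pooling of the intervening geometry — an independent
# route from the backprojection arithmetic.
influence_mask <- function(model, layer, row, col, to_layer) {
  blocks <- names(model$spec$blocks)
  shp <- layer_shapes(model$spec)
  ti <- match(to_layer, blocks)
  fi <- match(layer, blocks)
  g <- shp[[to_layer]]$pool
  mask <- matrix(FALSE, g, g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      x <- array(0, c(g, g, 1, 1))
      x[i, j, 1, 1] <- 1
      for (bi in seq(ti + 1, fi)) {
        geo <- model$spec$blocks[[blocks[bi]]]
        w <- array(1, c(geo$conv_k, geo$conv_k, dim(x)[3], 1))
        x <- orthonet:::cpp_conv_fwd(x, dim(x), w, dim(w), 0,
                                     geo$conv_s, geo$conv_p)
        x <- orthonet:::cpp_maxpool_fwd(x, dim(x), geo$pool_k, geo$pool_s,
                                        geo$pool_p)$y
      }
      mask[i, j] <- x[row, col, 1, 1] > 0
    }
  }
  mask
}

expect_rf_matches_influence <- function(model, layer, row, col, to_layer) {
  rf <- effective_receptive_field(model, layer, row, col, to_layer)
  m <- influence_mask(model, layer, row, col, to_layer)
  box <- matrix(FALSE, nrow(m), ncol(m))
  box[rf$rows[1]:rf$rows[2], rf$cols[1]:rf$cols[2]] <- TRUE
  expect_identical(box, m)
}

# Random pseudo-words of length 3..8 from a private stream.
random_words <- function(n, seed) {
  rng <- orthonet:::.seeded_rng(seed)
  vapply(seq_len(n), function(i)
    paste(letters[rng$int(rng$int(1, 6) + 2L, 26L)], collapse = ""),
    character(1))
}

# A population of synthetic units of each planted kind, at mid-frame
# positions so the factorial/spaced designs cover their tuning.
planted_population <- function(n, noise_sd = 0, seed = 1) {
  rng <- orthonet:::.seeded_rng(seed)
  kinds <- c("retinotopic", "ordinal_start", "ordinal_end",
             "space_bigram_left", "space_bigram_right", "word_position")
  lapply(seq_len(n), function(i) {
    kind <- kinds[(i - 1L) %% length(kinds) + 1L]
    switch(kind,
      retinotopic = synthetic_unit("retinotopic", "O",
                                   position_param = rng$int(1, 2) + 3L,
                                   tuning_width = 0.5, noise_sd = noise_sd),
      ordinal_start = synthetic_unit("ordinal_start", "O",
                                     position_param = rng$int(1, 2),
                                     noise_sd = noise_sd),
      ordinal_end = synthetic_unit("ordinal_end", "O",
                                   position_param = rng$int(1, 2),
                                   noise_sd = noise_sd),
      space_bigram_left = synthetic_unit("space_bigram_left", "O",
                                         rf = c(3L, 6L),
                                         noise_sd = noise_sd),
      space_bigram_right = synthetic_unit("space_bigram_right", "O",
                                          rf = c(3L, 6L),
                                          noise_sd = noise_sd),
      word_position = synthetic_unit("word_position",
                                     position_param = rng$int(1, 4),
                                     noise_sd = noise_sd))
  })
}

# Expected analysis label for a planted kind: what the factorial+spaced
# pipeline should recover.
planted_label <- function(kind) {
  switch(kind,
    retinotopic = "retinotopic",
    ordinal_start = , ordinal_end = "ordinal",
    space_bigram_left = , space_bigram_right = "space_bigram",
    word_position = "word_position")
}

# Run the factorial + spaced classification pipeline on one response pair.
pipeline_label <- function(resp_fact, resp_spaced, fact, spaced,
                           exclusion = 5) {
  cl <- classify_profile(resp_fact, fact, exclusion = exclusion)
  if (cl$category == "ordinal") {
    sp <- classify_profile(resp_spaced, spaced, exclusion = exclusion)
    rec <- spaced_reclassify(cl$category, sp, spaced)
    if (rec %in% c("space_bigram", "ordinal")) return(rec)
    return("ordinal")
  }
  cl$category
}
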