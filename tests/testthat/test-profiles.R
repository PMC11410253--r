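test_that("binarization uses a 30% relative threshold and the exclusion rule", {
  b <- binarize(matrix(c(10, 0, 0, 0), 2, 2), exclusion = 5)
  expect_equal(b$threshold, 3)
  expect_equal(b$binary, matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_false(b$excluded)
  expect_true(binarize(matrix(c(4.9, 0, 0, 0), 2, 2))$excluded)
  expect_true(binarize(matrix(7, 2, 2))$excluded)   # constant matrix
})

test_that("binary patterns (and categories) are invariant under positive affine rescaling", {
  rng <- orthonet:::.seeded_rng(31)
  for (i in 1:25) {
    raw <- matrix(rng$unif(20, 0, 10), 5, 4)
    a <- rng$unif(1, 0.5, 4); b0 <- rng$unif(1, 0, 5)
    r1 <- binarize(raw, exclusion = 0)
    r2 <- binarize(a * raw + b0, exclusion = 0)
    expect_identical(r1$binary, r2$binary)
    expect_identical(categorize(r1$binary)$category,
                     categorize(r2$binary)$category)
  }
})

test_that("response matrices index the factorial design and report missing stimuli", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  u <- synthetic_unit("ordinal_start", "O", position_param = 2)
  rm_ <- build_response_matrix(respond(u, fp), fp)
  expect_equal(dim(rm_$raw), c(5, 4))
  # ordinal-2 unit: support confined to column 2
  expect_true(all(which(rm_$raw > 0, arr.ind = TRUE)[, 2] == 2))
  expect_equal(build_response_matrix(rep(0, 20), fp)$raw, matrix(0, 5, 4))
  expect_error(build_response_matrix(rep(0, 19), fp), "missing stimulus")
})

test_that("categorizer labels canonical support patterns", {
  m <- matrix(0L, 5, 4); m[, 2] <- 1L
  expect_equal(categorize(m)$category, "ordinal")
  expect_equal(categorize(m)$preferred, 2)
  m <- matrix(0L, 5, 4); diag(m[1:4, ]) <- 1L
  expect_equal(categorize(m)$category, "retinotopic")
  m <- matrix(0L, 5, 4); m[3, ] <- 1L
  expect_equal(categorize(m)$category, "word_position")
  expect_equal(categorize(m)$preferred, 3)
  cb <- outer(1:5, 1:4, function(i, j) (i + j) %% 2L)
  expect_equal(categorize(cb)$category, "mixed")
  expect_equal(categorize(cb)$category,
               c("mixed", "ordinal", "retinotopic",
                 "word_position")[orthonet:::cpp_oracle_categorize(cb) + 1])
  z <- categorize(matrix(0L, 5, 4))
  expect_equal(z$category, "mixed")
  expect_true(z$empty_support)
})

test_that("layer summaries report proportions over non-excluded units", {
  df <- data.frame(layer = rep("IT", 10),
                   category = c(rep("ordinal", 3), rep("retinotopic", 5),
                                "mixed", "excluded"))
  s <- layer_summary(df)
  expect_equal(s$n[s$category == "ordinal"], 3)
  expect_equal(s$percent[s$category == "retinotopic"], 500 / 9,
               tolerance = 1e-10)
  expect_equal(sum(s$percent[s$category != "excluded"]), 100)
  e <- layer_summary(list(V1 = character(0)))
  expect_equal(e$layer, rep("V1", 5))
  expect_true(all(e$n == 0))
})

test_that("spaced probes separate space-bigram from true ordinal units", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  sp <- make_spaced_probe("O", "X", render = FALSE)
  classify2 <- function(u) {
    cl <- classify_profile(respond(u, fp), fp)
    spc <- classify_profile(respond(u, sp), sp)
    spaced_reclassify(cl$category, spc, sp)
  }
  expect_equal(classify2(synthetic_unit("space_bigram_left", "O",
                                        rf = c(3, 6))), "space_bigram")
  expect_equal(classify2(synthetic_unit("space_bigram_right", "O",
                                        rf = c(3, 6))), "space_bigram")
  expect_equal(classify2(synthetic_unit("ordinal_start", "O",
                                        position_param = 1)), "ordinal")
  expect_equal(classify2(synthetic_unit("retinotopic", "O",
                                        position_param = 4,
                                        tuning_width = 0.7)), "other")
  # excluded spaced matrix -> other
  weak <- classify_profile(respond(synthetic_unit("ordinal_start", "O",
                                                  position_param = 1,
                                                  gain = 1), sp), sp)
  expect_equal(spaced_reclassify("ordinal", weak, sp), "other")
})
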