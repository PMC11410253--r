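test_that("planted tuning produces the expected symbolic support", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  sp <- make_spaced_probe("O", "X", render = FALSE)
  # ordinal-1 unit: factorial support is exactly column 1
  u <- synthetic_unit("ordinal_start", "O", position_param = 1)
  m <- build_response_matrix(respond(u, fp), fp)$raw
  expect_equal(which(m > 0, arr.ind = TRUE)[, "col"],
               rep(1L, 5), ignore_attr = TRUE)
  expect_equal(sum(m > 0), 5)
  # ordinal-from-end mirrors to the last column
  ue <- synthetic_unit("ordinal_end", "O", position_param = 1)
  me <- build_response_matrix(respond(ue, fp), fp)$raw
  expect_true(all(which(me > 0, arr.ind = TRUE)[, "col"] == 4))
  # space-bigram support tracks blank adjacency on the spaced design:
  # active wherever the preferred letter's slot lies in the window,
  # irrespective of ordinal column
  ub <- synthetic_unit("space_bigram_left", "O", rf = c(3, 6))
  rb <- respond(ub, sp)
  expect_identical(rb > 0, sp$meta$pref_slot >= 3 & sp$meta$pref_slot <= 6)
  # the same unit on the unspaced design fires only at word-initial letters
  rbu <- respond(ub, fp)
  expect_identical(rbu > 0, fp$meta$col == 1 & fp$meta$pref_slot >= 3 &
                     fp$meta$pref_slot <= 6)
  # word-position unit fires for a whole row
  uw <- synthetic_unit("word_position", position_param = 3)
  rw <- respond(uw, fp)
  expect_identical(rw > 0, fp$meta$row == 3)
})

test_that("responses are deterministic given a seed and noise is truncated at zero", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  u <- synthetic_unit("ordinal_start", "O", position_param = 1,
                      noise_sd = 2)
  r1 <- respond(u, fp, seed = 42)
  r2 <- respond(u, fp, seed = 42)
  expect_identical(r1, r2)
  expect_false(identical(r1, respond(u, fp, seed = 43)))
  expect_true(all(r1 >= 0))
  u0 <- synthetic_unit("ordinal_start", "O", position_param = 1)
  expect_identical(respond(u0, fp, seed = 1), respond(u0, fp, seed = 2))
})

test_that("mixed units superpose their components", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  c1 <- synthetic_unit("ordinal_start", "O", position_param = 1)
  c2 <- synthetic_unit("ordinal_end", "O", position_param = 1)
  mx <- synthetic_unit("mixed", components = list(c1, c2),
                       weights = c(1, 0.5))
  expect_equal(respond(mx, fp),
               respond(c1, fp) + 0.5 * respond(c2, fp))
  expect_error(synthetic_unit("mixed"), "components")
  expect_error(synthetic_unit("ordinal_start", gain = 0), "positive")
})

test_that("populations are drop-in response stores with ground truth", {
  fp <- make_factorial_probe("O", "X", render = FALSE)
  sp <- make_spaced_probe("O", "X", render = FALSE)
  specs <- c(lapply(1:6, function(i)
    synthetic_unit("ordinal_start", "O", position_param = 1)),
    lapply(1:14, function(i)
      synthetic_unit("retinotopic", "O", position_param = 4,
                     tuning_width = 0.7)))
  pop <- generate_population(specs, list(factorial = fp, spaced = sp),
                             seed = 3)
  expect_equal(dim(pop$responses$factorial), c(20, 20))
  expect_equal(dim(pop$responses$spaced), c(12, 20))
  expect_equal(nrow(pop$truth), 20)
  cats <- vapply(seq_len(20), function(u)
    classify_profile(pop$responses$factorial[, u], fp)$category,
    character(1))
  tab <- layer_summary(data.frame(layer = "synth", category = cats))
  expect_equal(tab$n[tab$category == "ordinal"], 6)
  expect_equal(tab$n[tab$category == "retinotopic"], 14)
  expect_equal(tab$percent[tab$category == "ordinal"], 30)
})
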