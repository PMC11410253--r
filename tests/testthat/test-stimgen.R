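test_that("rendered words have the configured canvas, ink range and determinism", {
  s <- render_word("WORD", "sans", 50, c(0, 0), "upper", 224)
  expect_equal(dim(s$image), c(224, 224, 3))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_gt(sum(1 - s$image), 0)              # dark ink present
  s2 <- render_word("WORD", "sans", 50, c(0, 0), "upper", 224)
  expect_identical(s$image, s2$image)          # bit-identical re-render
  # blank frame carries zero ink
  b <- render_word("-", frame_slots = 8, canvas = 64)
  expect_equal(sum(1 - b$image), 0)
  # all channels equal (greyscale ink)
  expect_identical(s$image[, , 1], s$image[, , 3])
})

test_that("rendering errors are explicit", {
  expect_error(render_word("", canvas = 64), "empty")
  expect_error(render_word("A#B", canvas = 64), "glyph '#'")
  expect_error(render_word("WORD", size_pt = 70, offset = c(200, 0),
                           canvas = 224), "exceeds the canvas")
  expect_error(render_word("ABCDEFGHI", frame_slots = 8, canvas = 224),
               "frame too small")
  expect_error(render_word("WORD", font_id = "nosuch", canvas = 64),
               "unknown font")
})

test_that("dataset manifests have per-word counts, disjoint fonts, in-range variants", {
  m <- make_training_set(c("les", "toujours", "monde"), 40, 10, seed = 5,
                         canvas = 224)
  expect_equal(nrow(m), 3 * 50)
  expect_equal(unname(table(m$split)), c(3 * 10, 3 * 40),
               ignore_attr = TRUE)
  expect_true(all(m$font[m$split == "train"] %in% c("sans", "bold")))
  expect_true(all(m$font[m$split == "test"] %in%
                    c("slant", "serif", "backslant")))
  expect_true(all(m$dx >= -50 & m$dx <= 50))
  expect_true(all(m$dy >= -30 & m$dy <= 30))
  expect_true(all(m$size_pt >= 30 & m$size_pt <= 70))
  # same seed, identical manifest; different seed differs
  expect_identical(m, make_training_set(c("les", "toujours", "monde"),
                                        40, 10, seed = 5, canvas = 224))
  m2 <- make_training_set(c("les", "toujours", "monde"), 40, 10, seed = 6,
                          canvas = 224)
  expect_false(identical(m$dx, m2$dx))
  # every manifest row renders without ink overflow
  x <- render_dataset(m[sample.int(nrow(m), 25), ], 224)
  expect_equal(dim(x), c(224, 224, 3, 25))
  expect_error(make_training_set(character(0)), "empty")
  expect_error(make_training_set("les", fonts_train = c("sans"),
                                 fonts_test = c("sans")), "disjoint")
})

test_that("factorial probe design follows the printed string algebra", {
  p <- make_factorial_probe("o", "x", render = FALSE)
  expect_equal(length(p$strings), 20)
  expect_equal(p$strings[p$meta$row == 1 & p$meta$col == 1], "oxxx----")
  expect_equal(p$strings[p$meta$row == 5 & p$meta$col == 4], "----xxxo")
  for (s in p$strings) {
    ch <- strsplit(s, "")[[1]]
    expect_equal(sum(ch == "o"), 1)
    expect_equal(sum(ch == "x"), 3)
    expect_equal(sum(ch == "-"), 4)
  }
  expect_error(make_factorial_probe("o", "o"), "must differ")
  expect_error(make_factorial_probe("o", "x", frame_slots = 6),
               "frame too small")
})

test_that("spaced probe interleaves blanks and shifts whole patterns by row", {
  p <- make_spaced_probe("o", "x", render = FALSE)
  expect_equal(length(p$strings), 12)
  for (i in seq_len(12)) {
    ch <- strsplit(p$strings[i], "")[[1]]
    pos <- which(ch != "-")
    expect_equal(length(pos), 3)
    expect_equal(diff(pos), c(2, 2))           # one blank between letters
    expect_equal(pos[1], p$meta$row[i])        # row shifts the pattern
  }
  expect_equal(p$strings[p$meta$row == 1 & p$meta$col == 2], "x-o-x---")
})

test_that("single-letter grids and bigram sets have the factorial counts", {
  g <- make_single_letter_grid(LETTERS, render = FALSE)
  expect_equal(nrow(g$meta), 208)
  for (s in g$meta$string)
    expect_equal(sum(strsplit(s, "")[[1]] != "-"), 1)
  g1 <- make_single_letter_grid("Q", frame_slots = 1, render = FALSE)
  expect_equal(nrow(g1$meta), 1)
  bg <- make_bigram_set(n_bigrams = 49, seed = 2, render = FALSE)
  expect_equal(length(bg$bigrams), 49)
  expect_equal(anyDuplicated(bg$bigrams), 0)
  expect_error(make_bigram_set(n_bigrams = 1), "at least two")
})

test_that("localizer sets are labelled, partitioned and seed-stable", {
  loc <- make_localizer_set(c("les", "par"), n_words = 12,
                            n_per_category = 4, seed = 9, canvas = 64)
  expect_equal(length(loc$images), 12 + 4 * 4)
  expect_equal(unname(table(loc$labels)["word"]), 12, ignore_attr = TRUE)
  expect_setequal(unique(loc$labels),
                  c("word", "face", "house", "body", "tool"))
  loc2 <- make_localizer_set(c("les", "par"), n_words = 12,
                             n_per_category = 4, seed = 9, canvas = 64)
  expect_identical(loc$images[[3]], loc2$images[[3]])
  expect_identical(loc$images[[15]], loc2$images[[15]])
})
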