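test_that("design matrices place letters per scheme (worked 4-letter example)", {
  idx <- function(l, s) 26 * (s - 1) + match(l, letters)
  X <- build_design_matrix("WORD", "edge_aligned")$X
  expect_equal(which(X[1, ] == 1),
               idx(c("w", "o", "r", "d"), c(1, 2, 7, 8)), ignore_attr = TRUE)
  X <- build_design_matrix("WORD", "left_aligned")$X
  expect_equal(which(X[1, ] == 1),
               idx(c("w", "o", "r", "d"), c(1, 2, 3, 4)), ignore_attr = TRUE)
  X <- build_design_matrix("WORD", "word_centered")$X
  expect_equal(which(X[1, ] == 1),
               idx(c("w", "o", "r", "d"), c(3, 4, 5, 6)), ignore_attr = TRUE)
})

test_that("design matrices have 208 features, word-length row sums, and scheme-coincidence at 8 letters", {
  words <- random_words(40, seed = 2)
  for (sch in c("left_aligned", "word_centered", "edge_aligned")) {
    dm <- build_design_matrix(words, sch)
    expect_equal(ncol(dm$X), 208)
    expect_equal(unname(rowSums(dm$X)), nchar(words))
  }
  w8 <- c("toujours", "abcdefgh")
  Xs <- lapply(c("left_aligned", "word_centered", "edge_aligned"),
               function(s) build_design_matrix(w8, s)$X)
  expect_identical(Xs[[1]], Xs[[2]])
  expect_identical(Xs[[1]], Xs[[3]])
  expect_error(build_design_matrix("abcdefghi"), "longer than")
  expect_error(build_design_matrix("ab1"), "alphabetic")
})

test_that("lasso fit recovers a single active feature and flags degenerate responses", {
  words <- random_words(400, seed = 3)
  dm <- build_design_matrix(words, "left_aligned")
  Y <- dm$X[, "g1"] * 3
  f <- fit_encoding(Y, dm, seed = 1)
  expect_equal(names(which.max(f$b)), "g1")
  expect_gt(f$cv_r, 1 - 1e-5)
  fd <- fit_encoding(rep(2, 400), dm)
  expect_true(fd$degenerate)
  expect_equal(fd$cv_r, 0)
  expect_error(fit_encoding(Y[-1], dm), "length")
})

test_that("permuted responses give near-zero cross-validated correlation", {
  words <- random_words(300, seed = 4)
  dm <- build_design_matrix(words, "left_aligned")
  rng <- orthonet:::.seeded_rng(8)
  Y <- 2 * dm$X[, "g1"] + rng$norm(300, sd = 0.1)
  null_r <- vapply(1:15, function(i)
    fit_encoding(Y[rng$perm(300)], dm, seed = i)$cv_r, numeric(1))
  expect_lt(abs(mean(null_r)), 0.1)
  expect_gt(fit_encoding(Y, dm, seed = 1)$cv_r, 0.8)
})

test_that("scheme comparison flags ties for position-invariant units and is word-order invariant", {
  words <- random_words(250, seed = 6)
  u <- synthetic_unit("letter_invariant", "K")
  Y <- respond(u, words)
  cs <- compare_schemes(matrix(Y, ncol = 1), words, seed = 2)
  expect_true(cs$tie[1])
  # shuffling word order (rows permuted consistently) keeps cv_r
  rng <- orthonet:::.seeded_rng(9)
  ord <- rng$perm(250)
  u2 <- synthetic_unit("ordinal_start", "R", position_param = 1,
                       noise_sd = 0.5)
  Y2 <- respond(u2, words, seed = 5)
  a <- compare_schemes(matrix(Y2, ncol = 1), words, seed = 3)
  b <- compare_schemes(matrix(Y2[ord], ncol = 1), words[ord], seed = 3)
  expect_equal(a$cv_r_edge_aligned, b$cv_r_edge_aligned, tolerance = 0.05)
  expect_equal(a$winner, b$winner)
})

test_that("position tuning groups units by peak slot and normalizes to 1", {
  words <- random_words(300, seed = 12)
  dm <- build_design_matrix(words, "left_aligned")
  fits <- lapply(c("a1", "b1", "c4"), function(ft) {
    Y <- 2 * dm$X[, ft]
    fit_encoding(Y, dm, seed = 2)
  })
  pt <- position_tuning(fits)
  expect_equal(vapply(pt, `[[`, numeric(1), "group"), c(1, 4))
  expect_equal(vapply(pt, function(g) max(g$curve), numeric(1)), c(1, 1))
  expect_equal(pt[[1]]$n_units, 2)
  # all-zero coefficients are dropped with a warning
  zf <- fits[[1]]; zf$b[] <- 0
  expect_warning(position_tuning(c(fits, list(zf))), "all-zero")
})
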