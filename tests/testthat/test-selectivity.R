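test_that("localizer contrast flags units above every category by k sd", {
  # unit 1: word mean 10, categories mean 0 sd 0.1 -> selective
  # unit 2: identical responses everywhere -> not selective
  words <- cbind(rep(10, 6), rep(2, 6))
  cats <- list(face = cbind(c(-.1, .1, 0, -.1, .1, 0), rep(2, 6)),
               house = cbind(c(.1, -.1, 0, .1, -.1, 0), rep(2, 6)))
  res <- find_word_selective(words, cats)
  expect_equal(res$selective, c(TRUE, FALSE))
  expect_error(find_word_selective(words, list(face = cats$face[, 1,
                                                                drop = FALSE])),
               "unit sets differ")
  expect_error(find_word_selective(words,
                                   list(face = cats$face[1, , drop = FALSE])),
               ">= 2 stimuli")
})

test_that("planted selective units are recovered exactly at zero noise", {
  rng <- orthonet:::.seeded_rng(21)
  nu <- 1000; planted <- sort(rng$sample_idx(nu, 50))
  words <- matrix(rng$unif(20 * nu), 20, nu)
  cats <- lapply(c(face = 1, house = 2, body = 3, tool = 4), function(i)
    matrix(rng$unif(10 * nu), 10, nu))
  words[, planted] <- words[, planted] + 10
  res <- find_word_selective(words, cats)
  # direct inequality oracle per unit
  oracle <- vapply(seq_len(nu), function(u)
    all(vapply(cats, function(m)
      mean(words[, u]) > mean(m[, u]) + 3 * sd(m[, u]), logical(1))),
    logical(1))
  expect_identical(res$selective, oracle)
  expect_true(all(planted %in% which(res$selective)))
})

test_that("selectivity shrinks with k_sd and is affine-invariant", {
  rng <- orthonet:::.seeded_rng(5)
  words <- matrix(rng$unif(20 * 100, 0, 3), 20, 100)
  cats <- list(face = matrix(rng$unif(10 * 100), 10, 100),
               tool = matrix(rng$unif(10 * 100), 10, 100))
  sets <- lapply(c(1, 2, 3, 5), function(k)
    which(find_word_selective(words, cats, k_sd = k)$selective))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # shift all responses of every store by a constant, scale positively
  res0 <- find_word_selective(words, cats)
  res1 <- find_word_selective(2.5 * words + 7,
                              lapply(cats, function(m) 2.5 * m + 7))
  expect_identical(res0$selective, res1$selective)
})

test_that("letter tuning picks argmax/argmin of per-letter maxima", {
  g <- make_single_letter_grid(LETTERS, render = FALSE)
  # indicator of Q at any slot
  r <- as.numeric(g$meta$letter == "Q")
  lt <- letter_tuning(r, g$meta)
  expect_equal(lt$best_letter, "Q")
  expect_equal(dim(lt$table), c(26, 8))
  # planted gaussian over slots peaked at letter g, minimum at letter z
  peak <- exp(-0.5 * ((g$meta$slot - 4) / 2)^2)
  amp <- ifelse(g$meta$letter == "G", 2, 1)
  amp[g$meta$letter == "Z"] <- 0.1
  lt2 <- letter_tuning(amp * peak, g$meta)
  expect_equal(lt2$best_letter, "G")
  expect_equal(lt2$worst_letter, "Z")
  expect_error(letter_tuning(r[-1], g$meta), "mismatch")
  expect_error(letter_tuning(r[-1], g$meta[-1, ]), "missing")
})

test_that("per-layer selective counts and percentages add up", {
  res <- list(
    V4 = data.frame(unit = 1:10, selective = rep(c(TRUE, FALSE), 5)),
    IT = data.frame(unit = 1:4, selective = rep(FALSE, 4)))
  tab <- count_selective_by_layer(res)
  expect_equal(tab$n_selective, c(5, 0))
  expect_equal(tab$percent, c(50, 0))
  empty <- count_selective_by_layer(list(V1 = data.frame(
    unit = integer(), selective = logical())))
  expect_equal(empty$n_selective, 0)
})
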