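test_that("filter weight sums collapse each kernel to one number per input channel", {
  model <- build_network(network_spec(64, c(4L, 8L, 16L, 32L)), 5, seed = 2)
  ws <- filter_weight_sums(model, "IT", 3)
  expect_length(ws, 16)
  expect_equal(ws[5], sum(model$blocks$IT$W[, , 5, 3]))
  model$blocks$IT$W[, , 2, 3] <- 0
  expect_equal(filter_weight_sums(model, "IT", 3)[2], 0)
  model$blocks$IT$W[, , 2, 3] <- matrix(c(1, 0, 0, -1, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(filter_weight_sums(model, "IT", 3)[2], 0)
  expect_error(filter_weight_sums(model, "nope", 1), "no convolution")
})

test_that("channel drive and attribution match a hand computation on a toy store", {
  model <- build_network(network_spec(64, c(4L, 8L, 16L, 32L)), 5, seed = 2)
  target <- list(layer = "IT", channel = 3, row = 1, col = 1)
  dims <- c(4L, 4L, 16L)                    # V4 grid at this scale
  nu <- prod(dims)
  rng <- orthonet:::.seeded_rng(44)
  acts <- matrix(rng$unif(20 * nu, 0, 8), 20, nu)
  wsel <- rng$unif(nu) < 0.4
  store <- structure(list(layers = list(V4 = acts), dims = list(V4 = dims),
                          n_stimuli = 20L), class = "activation_store")
  cd <- channel_drive(model, target, "V4", store, wsel)
  # independent route: nested loops over the receptive field
  rf <- effective_receptive_field(model, "IT", 1, 1, "V4")
  for (ch in c(1, 7, 16)) {
    best <- 0; found <- FALSE
    for (r in rf$rows[1]:rf$rows[2]) for (cc in rf$cols[1]:rf$cols[2]) {
      u <- unit_index(dims, ch, r, cc)
      if (wsel[u]) { found <- TRUE; best <- max(best, max(acts[, u])) }
    }
    expect_equal(cd$drive[ch], best)
    expect_equal(cd$no_unit_in_rf[ch], !found)
  }
  rep_ <- attribute(model, target, "V4", store, wsel, k = 2)
  expect_equal(rep_$product, filter_weight_sums(model, "IT", 3) * cd$drive)
  expect_true(all(rep_$product[rep_$top_excitatory] >=
                    max(0, rep_$product[-rep_$top_excitatory])))
  # planted dominant channel ranks top excitatory
  model2 <- model
  model2$blocks$IT$W[, , 9, 3] <- 1
  acts2 <- acts; wsel2 <- wsel
  wsel2[unit_index(dims, 9, 2, 2)] <- TRUE
  acts2[, unit_index(dims, 9, 2, 2)] <- 100
  store2 <- structure(list(layers = list(V4 = acts2),
                           dims = list(V4 = dims), n_stimuli = 20L),
                      class = "activation_store")
  rep2 <- attribute(model2, target, "V4", store2, wsel2)
  expect_equal(rep2$top_excitatory[1], 9)
  # negating all kernels swaps excitatory and inhibitory lists
  model3 <- model2
  model3$blocks$IT$W <- -model3$blocks$IT$W
  rep3 <- attribute(model3, target, "V4", store2, wsel2)
  expect_setequal(rep3$top_inhibitory,
                  rep2$top_excitatory[seq_along(rep3$top_inhibitory)])
  # all-zero activations -> zero drives, empty top lists with flag
  store0 <- structure(list(layers = list(V4 = acts * 0),
                           dims = list(V4 = dims), n_stimuli = 20L),
                      class = "activation_store")
  rep0 <- attribute(model, target, "V4", store0, wsel)
  expect_true(rep0$all_drives_zero)
  expect_length(rep0$top_excitatory, 0)
})

test_that("V2-level attribution runs through the identical code path", {
  model <- build_network(network_spec(64, c(4L, 8L, 16L, 32L)), 5, seed = 2)
  dims <- c(8L, 8L, 8L)                     # V2 grid at this scale
  rng <- orthonet:::.seeded_rng(45)
  store <- structure(list(layers = list(V2 = matrix(rng$unif(20 * prod(dims)),
                                                    20, prod(dims))),
                          dims = list(V2 = dims), n_stimuli = 20L),
                     class = "activation_store")
  rep_ <- attribute(model, list(layer = "V4", channel = 2, row = 2, col = 3),
                    "V2", store, rep(TRUE, prod(dims)))
  expect_length(rep_$weight_sums, 8)
  expect_length(rep_$drive, 8)
})

test_that("first-layer spectra classify constant, checkerboard and planted Gabor kernels", {
  model <- build_network(network_spec(64, c(8L, 8L, 16L, 32L)), 5, seed = 3)
  W <- model$blocks$V1$W                    # 7x7x3x8
  gabor <- function(freq, theta = 0) {
    g <- outer(1:7, 1:7, function(i, j)
      exp(-((i - 4)^2 + (j - 4)^2) / 8) *
        cos(2 * pi * freq * ((i - 4) * cos(theta) + (j - 4) * sin(theta))))
    g
  }
  for (c in 1:3) {
    W[, , c, 1] <- 1                                        # constant
    W[, , c, 2] <- outer(1:7, 1:7, function(i, j) (-1)^(i + j))
    W[, , c, 3] <- gabor(1 / 7)                             # low
    W[, , c, 4] <- gabor(3 / 7)                             # high
  }
  model$blocks$V1$W <- W
  sp <- v1_filter_spectrum(model)
  expect_equal(sp$peak_freq[1], 0)
  expect_equal(sp$class[1], "low")
  expect_equal(sp$peak_freq[2], sqrt(2) * 3 / 7, tolerance = 1e-9)
  expect_equal(sp$class[2], "high")
  expect_lt(sp$peak_freq[3], sp$peak_freq[4])
  expect_equal(sp$class[4], "high")
})
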