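# Architecture geometry, training mechanics, activation recording, and
# receptive-field backprojection. Small canvases keep these fast; the
# full-size geometry is asserted in the acceptance suite.

test_that("block shapes halve spatially and match the configured widths", {
  spec <- network_spec(64, c(4L, 8L, 16L, 32L))
  shp <- layer_shapes(spec)
  expect_equal(vapply(shp, `[[`, integer(1), "pool"),
               c(V1 = 16L, V2 = 8L, V4 = 4L, IT = 2L))
  model <- build_network(spec, 5)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fw <- cornet_forward(model, x, keep = c("V2", "IT"))
  expect_equal(dim(fw$acts$V2), c(8, 8, 8, 2))
  expect_equal(dim(fw$acts$IT), c(2, 2, 32, 2))
  expect_equal(dim(fw$logits), c(2, 5))
})

test_that("avgIT equals the spatial mean of IT and recording is deterministic", {
  model <- build_network(network_spec(64, c(4L, 8L, 16L, 32L)), 5)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  st <- record_activations(model, x, c("IT", "avgIT"))
  it <- st$layers$IT; d <- st$dims$IT
  for (n in 1:3) {
    a <- array(it[n, ], d)
    expect_equal(st$layers$avgIT[n, ], apply(a, 3, mean))
  }
  st2 <- record_activations(model, x, c("IT", "avgIT"))
  expect_identical(st$layers$IT, st2$layers$IT)
  expect_error(record_activations(model, x, "V9"), "unknown layer")
})

test_that("training reduces the loss, is seed-reproducible, and epochs = 0 leaves weights unchanged", {
  spec <- network_spec(32, c(4L, 8L, 8L, 16L))
  model <- build_network(spec, 2, seed = 3)
  rng <- orthonet:::.seeded_rng(11)
  n <- 40
  x <- array(rng$unif(32 * 32 * 3 * n), c(32, 32, 3, n))
  # separable toy task: dark vs light left half
  y <- ifelse(apply(x[, 1:16, , ], 4, mean) > 0.5, 1L, 2L)
  m0 <- train_cornet(model, x, y, training_schedule(0))
  expect_identical(m0$blocks, model$blocks)
  sch <- training_schedule(4, batch_size = 10)
  m1 <- train_cornet(model, x, y, sch, seed = 7)
  log1 <- attr(m1, "metrics")
  expect_lt(log1$loss[4], log1$loss[1])
  m2 <- train_cornet(model, x, y, sch, seed = 7)
  expect_identical(m1$blocks$V1$W, m2$blocks$V1$W)
  expect_error(train_cornet(model, x[, , , 0, drop = FALSE], integer(0), sch),
               "empty")
})

test_that("learning-rate schedule decays by gamma every step", {
  sch <- training_schedule(25)
  expect_equal(sch$lr0, 0.01)
  expect_equal(sch$lr_step, 10L)
  expect_equal(sch$lr_gamma, 0.1)
  lr <- sch$lr0 * sch$lr_gamma^(((1:25) - 1) %/% sch$lr_step)
  expect_equal(lr[c(1, 10, 11, 21)], c(0.01, 0.01, 0.001, 1e-04))
})

test_that("output extension preserves pre-existing logits and rejects bad sizes", {
  model <- build_network(network_spec(32, c(4L, 8L, 8L, 16L)), 6, seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  before <- cornet_forward(model, x)$logits
  ext <- extend_output(model, 4)
  after <- cornet_forward(ext, x)$logits
  expect_equal(ncol(after), 10)
  expect_equal(after[, 1:6, drop = FALSE], before, tolerance = 1e-12)
  expect_error(extend_output(model, 0), "positive")
})

test_that("backprojected receptive fields match brute-force influence masks", {
  model <- build_network(network_spec(224), 2, seed = 1)
  # central IT unit spans 5x5 on the V4 grid
  rf <- effective_receptive_field(model, "IT", 4, 4, "V4")
  expect_equal(rf$side, 5L)
  # identity projection
  expect_equal(effective_receptive_field(model, "V4", 3, 9, "V4"),
               list(rows = c(3, 3), cols = c(9, 9), side = 1L))
  # corner/edge units: box equals the influence mask (clipped at borders)
  expect_rf_matches_influence(model, "IT", 1, 1, "V4")
  expect_rf_matches_influence(model, "IT", 7, 2, "V4")
  expect_rf_matches_influence(model, "IT", 4, 4, "V4")
  expect_rf_matches_influence(model, "V4", 14, 1, "V2")
  expect_error(effective_receptive_field(model, "V2", 1, 1, "IT"),
               "ancestor")
})
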