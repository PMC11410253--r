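# A compact ventral-stream-style convolutional network (CORnet-Z family):
# four blocks named V1, V2, V4, IT, each conv -> rectification -> max-pool,
# followed by a global average pool over IT ("avgIT") and a fully connected
# readout. Forward, backward and SGD training are implemented on the compiled
# primitives in src/convnet.cpp. With the default widths (64, 128, 256, 512)
# and a 224x224x3 input the block outputs are V1 64x56x56, V2 128x28x28,
# V4 256x14x14 and IT 512x7x7.

.out_size <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Network architecture specification
#'
#' @param canvas input image edge in pixels.
#' @param widths output channels of the four blocks (V1, V2, V4, IT).
#' @param in_channels input image channels.
#' @param normalize input normalization constants `c(mean, sd)` applied to
#'   every image before the first convolution (defaults match the synthetic
#'   stimulus statistics: dark ink on a light background).
#' @return A `network_spec`: block list with convolution (kernel, stride,
#'   padding) and pooling geometry, plus the canvas.
#' @export
network_spec <- function(canvas = 224L, widths = c(64L, 128L, 256L, 512L),
                         in_channels = 3L, normalize = c(0.92, 0.25)) {
  stopifnot(length(widths) == 4)
  mk <- function(out, k, s, p) list(out = as.integer(out), conv_k = k,
                                    conv_s = s, conv_p = p,
                                    pool_k = 3L, pool_s = 2L, pool_p = 1L)
  spec <- structure(list(
    canvas = as.integer(canvas), in_channels = as.integer(in_channels),
    normalize = normalize,
    blocks = list(V1 = mk(widths[1], 7L, 2L, 3L),
                  V2 = mk(widths[2], 3L, 1L, 1L),
                  V4 = mk(widths[3], 3L, 1L, 1L),
                  IT = mk(widths[4], 3L, 1L, 1L))),
    class = "network_spec")
  shp <- layer_shapes(spec)   # validates
  if (any(vapply(shp, function(s) any(unlist(s) < 1), logical(1))))
    stop("spec incompatible with canvas ", canvas, ": block ",
         names(shp)[vapply(shp, function(s) any(unlist(s) < 1), logical(1))][1],
         " collapses to zero size", call. = FALSE)
  spec
}

#' Per-block output shapes
#'
#' @param spec a `network_spec`.
#' @return Named list per block: `conv` (pre-pool spatial size), `pool`
#'   (block output spatial size), `channels`.
#' @export
layer_shapes <- function(spec) {
  n <- spec$canvas
  out <- list()
  for (nm in names(spec$blocks)) {
    b <- spec$blocks[[nm]]
    cv <- .out_size(n, b$conv_k, b$conv_s, b$conv_p)
    pl <- .out_size(cv, b$pool_k, b$pool_s, b$pool_p)
    out[[nm]] <- list(conv = cv, pool = pl, channels = b$out)
    n <- pl
  }
  out
}

#' Build a network with randomly initialized weights
#'
#' @param spec a [network_spec()].
#' @param n_out number of output categories.
#' @param seed seed for the (He-style normal) weight initialization.
#' @return A `cornet_model`.
#' @export
build_network <- function(spec, n_out, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), n_out >= 1)
  rng <- .seeded_rng(seed)
  blocks <- list()
  inc <- spec$in_channels
  for (nm in names(spec$blocks)) {
    b <- spec$blocks[[nm]]
    k <- b$conv_k
    fan_in <- k * k * inc
    W <- array(rng$norm(k * k * inc * b$out, sd = sqrt(2 / fan_in)),
               dim = c(k, k, inc, b$out))
    blocks[[nm]] <- list(W = W, b = numeric(b$out))
    inc <- b$out
  }
  shp <- layer_shapes(spec)
  c_it <- shp$IT$channels
  fc <- list(W = matrix(rng$norm(c_it * n_out, sd = sqrt(2 / c_it)),
                        c_it, n_out),
             b = numeric(n_out))
  structure(list(spec = spec, blocks = blocks, fc = fc,
                 n_out = as.integer(n_out)),
            class = "cornet_model")
}

#' @export
print.cornet_model <- function(x, ...) {
  shp <- layer_shapes(x$spec)
  cat(sprintf("<cornet_model canvas=%d, n_out=%d>\n", x$spec$canvas, x$n_out))
  for (nm in names(shp))
    cat(sprintf("  %-3s %4d x %2d x %2d\n", nm, shp[[nm]]$channels,
                shp[[nm]]$pool, shp[[nm]]$pool))
  invisible(x)
}

# Forward through the four blocks. Returns block outputs (post-pool) for the
# layers in `keep`, plus caches for backprop when `cache = TRUE`.
.forward_blocks <- function(model, x, keep = character(), cache = FALSE) {
  nz <- model$spec$normalize
  if (!is.null(nz)) x <- (x - nz[1]) / nz[2]
  acts <- list(); caches <- list()
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]; g <- model$spec$blocks[[nm]]
    z <- cpp_conv_fwd(x, dim(x), blk$W, dim(blk$W), blk$b, g$conv_s, g$conv_p)
    z[z < 0] <- 0
    pl <- cpp_maxpool_fwd(z, dim(z), g$pool_k, g$pool_s, g$pool_p)
    if (cache)
      caches[[nm]] <- list(x = x, mask = z > 0, argmax = pl$argmax,
                           zdim = dim(z))
    x <- pl$y
    if (nm %in% keep) acts[[nm]] <- x
  }
  list(out = x, acts = acts, caches = caches)
}

#' Forward pass
#'
#' @param model a `cornet_model`.
#' @param x image batch (H, W, C, N).
#' @param keep block names whose outputs to return alongside the logits.
#' @return List with `logits` (N x n_out), `avgIT` (N x channels) and `acts`.
#' @export
cornet_forward <- function(model, x, keep = character()) {
  fw <- .forward_blocks(model, x, keep = keep)
  it <- fw$out
  d <- dim(it)
  avg <- t(colMeans(matrix(it, d[1] * d[2], d[3] * d[4]))) # (C*N) means
  avg <- matrix(avg, d[4], d[3], byrow = TRUE)             # N x C
  logits <- sweep(avg %*% model$fc$W, 2, model$fc$b, "+")
  list(logits = logits, avgIT = avg, acts = fw$acts)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One forward+backward pass; returns loss and parameter gradients.
.loss_grads <- function(model, x, y) {
  fw <- .forward_blocks(model, x, cache = TRUE)
  it <- fw$out; d <- dim(it)
  n <- d[4]; cch <- d[3]; hw <- d[1] * d[2]
  avg <- matrix(colMeans(matrix(it, hw, cch * n)), n, cch, byrow = TRUE)
  logits <- sweep(avg %*% model$fc$W, 2, model$fc$b, "+")
  p <- .softmax(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlog <- p
  dlog[cbind(seq_len(n), y)] <- dlog[cbind(seq_len(n), y)] - 1
  dlog <- dlog / n
  grads <- list(fc = list(W = crossprod(avg, dlog), b = colSums(dlog)))
  davg <- dlog %*% t(model$fc$W)                     # N x C
  dit <- array(rep(as.vector(t(davg)) / hw, each = hw), dim = d)
  dy <- dit
  for (nm in rev(names(model$blocks))) {
    blk <- model$blocks[[nm]]; g <- model$spec$blocks[[nm]]
    ch <- fw$caches[[nm]]
    dz <- cpp_maxpool_bwd(ch$argmax, dy, ch$zdim)
    dz[!ch$mask] <- 0
    bw <- cpp_conv_bwd(ch$x, dim(ch$x), blk$W, dim(blk$W), dz,
                       g$conv_s, g$conv_p)
    grads[[nm]] <- list(W = bw$dw, b = bw$db)
    dy <- bw$dx
  }
  list(loss = loss, grads = grads)
}

#' Training schedule
#'
#' Stochastic gradient descent on categorical cross-entropy with a step-decay
#' learning-rate schedule: the rate starts at `lr0` and is multiplied by
#' `lr_gamma` every `lr_step` epochs.
#'
#' @param epochs number of epochs.
#' @param lr0 initial learning rate (default 0.01).
#' @param lr_step epochs between decays (default 10).
#' @param lr_gamma decay factor (default 0.1).
#' @param momentum SGD momentum.
#' @param batch_size minibatch size.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(epochs, lr0 = 0.01, lr_step = 10L,
                              lr_gamma = 0.1, momentum = 0.9,
                              batch_size = 32L) {
  stopifnot(epochs >= 0, lr0 > 0, lr_step >= 1)
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 momentum = momentum, batch_size = as.integer(batch_size)),
            class = "training_schedule")
}

#' Train a network
#'
#' @param model a `cornet_model`.
#' @param x training images (H, W, C, N); N must be positive.
#' @param y integer labels in 1..n_out.
#' @param schedule a [training_schedule()].
#' @param seed seed controlling minibatch shuffling.
#' @param tests optional named list of held-out sets `list(x =, y =)`; top-1
#'   accuracy on each is logged per epoch (e.g. one entry per stimulus
#'   domain: objects, words).
#' @param verbose print per-epoch metrics.
#' @return The trained model, with a `metrics` attribute: a data.frame of
#'   per-epoch loss, learning rate and per-domain accuracy.
#' @export
train_cornet <- function(model, x, y, schedule, seed = 1L, tests = list(),
                         verbose = FALSE) {
  n <- dim(x)[4]
  if (is.null(n) || n == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(y) == n, all(y >= 1), all(y <= model$n_out))
  rng <- .seeded_rng(seed)
  vel <- rapply(c(model$blocks, list(fc = model$fc)),
                function(p) p * 0, how = "replace")
  logs <- list()
  for (ep in seq_len(schedule$epochs)) {
    lr <- schedule$lr0 * schedule$lr_gamma^((ep - 1) %/% schedule$lr_step)
    ord <- rng$perm(n)
    losses <- c()
    for (b0 in seq(1, n, by = schedule$batch_size)) {
      idx <- ord[b0:min(b0 + schedule$batch_size - 1, n)]
      lg <- .loss_grads(model, x[, , , idx, drop = FALSE], y[idx])
      losses <- c(losses, lg$loss)
      for (nm in names(model$blocks)) {
        for (p in c("W", "b")) {
          vel[[nm]][[p]] <- schedule$momentum * vel[[nm]][[p]] -
            lr * lg$grads[[nm]][[p]]
          model$blocks[[nm]][[p]] <- model$blocks[[nm]][[p]] + vel[[nm]][[p]]
        }
      }
      for (p in c("W", "b")) {
        vel$fc[[p]] <- schedule$momentum * vel$fc[[p]] - lr * lg$grads$fc[[p]]
        model$fc[[p]] <- model$fc[[p]] + vel$fc[[p]]
      }
    }
    row <- data.frame(epoch = ep, lr = lr, loss = mean(losses))
    for (tn in names(tests))
      row[[paste0("acc_", tn)]] <-
        mean(predict_cornet(model, tests[[tn]]$x) == tests[[tn]]$y)
    logs[[ep]] <- row
    if (verbose)
      message(paste(utils::capture.output(print(row, row.names = FALSE)),
                    collapse = "\n"))
  }
  attr(model, "metrics") <- if (length(logs)) do.call(rbind, logs) else
    data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  model
}

#' Predict top-1 classes
#'
#' @param model a `cornet_model`.
#' @param x image batch (H, W, C, N).
#' @param chunk images per forward chunk.
#' @return Integer vector of predicted labels.
#' @export
predict_cornet <- function(model, x, chunk = 128L) {
  n <- dim(x)[4]
  out <- integer(n)
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, n)
    lg <- cornet_forward(model, x[, , , idx, drop = FALSE])$logits
    out[idx] <- max.col(lg, ties.method = "first")
  }
  out
}

#' Extend the output layer with new categories
#'
#' Appends `n_new` output units, fully connected to avgIT, leaving every
#' existing weight untouched. New rows use a small-variance zero-mean
#' initialization so pre-existing logits are unchanged at step 0.
#'
#' @param model a trained `cornet_model`.
#' @param n_new number of categories to add (> 0).
#' @param init_sd standard deviation of the new output weights.
#' @param seed initialization seed.
#' @return The extended model.
#' @export
extend_output <- function(model, n_new, init_sd = 1e-3, seed = 1L) {
  if (n_new <= 0) stop("n_new must be positive", call. = FALSE)
  rng <- .seeded_rng(seed)
  c_it <- nrow(model$fc$W)
  model$fc$W <- cbind(model$fc$W,
                      matrix(rng$norm(c_it * n_new, sd = init_sd), c_it, n_new))
  model$fc$b <- c(model$fc$b, numeric(n_new))
  model$n_out <- model$n_out + as.integer(n_new)
  model
}

# ---- activation recording -------------------------------------------------

#' Record layer activations for a stimulus set
#'
#' Stores post-rectification, post-pooling block outputs per stimulus;
#' "avgIT" is the channel-wise spatial average of IT. Each layer is stored as
#' an n_stimuli x n_units matrix (units vectorized in (row, col, channel)
#' array order) with the grid dimensions kept as metadata.
#'
#' @param model a `cornet_model`.
#' @param stimuli list of `rendered_stimulus` objects or an (H, W, C, N)
#'   batch array.
#' @param layers layer names among V1, V2, V4, IT, avgIT.
#' @param chunk stimuli per forward chunk.
#' @return An `activation_store`: list with `layers` (named matrices),
#'   `dims` (named `c(rows, cols, channels)` per grid layer) and `n_stimuli`.
#' @export
record_activations <- function(model, stimuli,
                               layers = c("V4", "IT", "avgIT"),
                               chunk = 64L) {
  known <- c(names(model$blocks), "avgIT")
  bad <- setdiff(layers, known)
  if (length(bad)) stop("unknown layer name: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x <- if (is.array(stimuli)) stimuli else as_image_batch(stimuli)
  n <- dim(x)[4]
  keep <- setdiff(layers, "avgIT")
  if ("avgIT" %in% layers) keep <- union(keep, "IT")
  shp <- layer_shapes(model$spec)
  store <- list(layers = list(), dims = list(), n_stimuli = n)
  for (nm in layers) {
    nu <- if (nm == "avgIT") shp$IT$channels else
      shp[[nm]]$pool^2 * shp[[nm]]$channels
    store$layers[[nm]] <- matrix(0, n, nu)
    store$dims[[nm]] <- if (nm == "avgIT") c(1L, 1L, shp$IT$channels) else
      c(shp[[nm]]$pool, shp[[nm]]$pool, shp[[nm]]$channels)
  }
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, n)
    fw <- .forward_blocks(model, x[, , , idx, drop = FALSE], keep = keep)
    for (nm in layers) {
      if (nm == "avgIT") {
        it <- fw$acts$IT; d <- dim(it)
        avg <- matrix(colMeans(matrix(it, d[1] * d[2], d[3] * d[4])),
                      d[4], d[3], byrow = TRUE)
        store$layers$avgIT[idx, ] <- avg
      } else {
        a <- fw$acts[[nm]]; d <- dim(a)
        store$layers[[nm]][idx, ] <- t(matrix(a, d[1] * d[2] * d[3], d[4]))
      }
    }
  }
  structure(store, class = "activation_store")
}

#' Flat unit index from grid coordinates (and back)
#'
#' Units of a grid layer are vectorized in (row, col, channel) array order.
#'
#' @param dims layer dims `c(rows, cols, channels)`.
#' @param channel,row,col 1-based coordinates.
#' @return `unit_index`: the flat 1-based index. `unit_address`: a list with
#'   `channel`, `row`, `col`.
#' @export
unit_index <- function(dims, channel, row, col) {
  as.integer(row + (col - 1L) * dims[1] + (channel - 1L) * dims[1] * dims[2])
}

#' @rdname unit_index
#' @param index flat 1-based unit index.
#' @export
unit_address <- function(dims, index) {
  i <- index - 1L
  row <- i %% dims[1]
  col <- (i %/% dims[1]) %% dims[2]
  ch <- i %/% (dims[1] * dims[2])
  list(channel = ch + 1L, row = row + 1L, col = col + 1L)
}

# ---- receptive-field backprojection --------------------------------------

# Invert one (kernel, stride, pad) op: output index range -> input range,
# clipped to the input grid.
.invert_op <- function(rng, k, s, p, in_size) {
  lo <- (rng[1] - 1L) * s - p + 1L
  hi <- (rng[2] - 1L) * s - p + k
  c(max(1L, lo), min(in_size, hi))
}

#' Effective receptive field by exact backprojection
#'
#' Projects one spatial unit of `layer` back onto the output grid of the
#' earlier `to_layer`, composing the inverse geometry of every intervening
#' convolution and pooling op and clipping at grid borders. For `layer =
#' "avgIT"` the projection starts from the full IT grid.
#'
#' @param model a `cornet_model` (only its geometry is used).
#' @param layer block name (or "avgIT") of the target unit.
#' @param row,col 1-based spatial position of the target unit (ignored for
#'   avgIT).
#' @param to_layer earlier block name whose grid the field is expressed on.
#' @return List with `rows`, `cols` (index ranges on the `to_layer` grid) and
#'   `side` (bounding-box side, the larger of the two extents).
#' @export
effective_receptive_field <- function(model, layer, row = NULL, col = NULL,
                                      to_layer) {
  blocks <- names(model$spec$blocks)
  shp <- layer_shapes(model$spec)
  from_idx <- if (identical(layer, "avgIT")) length(blocks) + 1L else
    match(layer, blocks)
  to_idx <- match(to_layer, blocks)
  if (is.na(from_idx) || is.na(to_idx))
    stop("unknown layer name", call. = FALSE)
  if (to_idx > min(from_idx, length(blocks)))
    stop("to_layer must be an ancestor of the unit's layer", call. = FALSE)
  if (identical(layer, "avgIT")) {
    g <- shp$IT$pool
    rows <- c(1L, g); cols <- c(1L, g)
    from_idx <- length(blocks)
  } else {
    if (to_idx == from_idx)
      return(list(rows = c(row, row), cols = c(col, col), side = 1L))
    rows <- c(row, row); cols <- c(col, col)
  }
  if (identical(layer, "avgIT") && to_idx == length(blocks))
    return(list(rows = rows, cols = cols, side = diff(rows) + 1L))
  for (bi in seq(from_idx, to_idx + 1L)) {
    nm <- blocks[bi]
    g <- model$spec$blocks[[nm]]
    conv_size <- shp[[nm]]$conv
    in_size <- if (bi == 1L) model$spec$canvas else shp[[blocks[bi - 1L]]]$pool
    rows <- .invert_op(rows, g$pool_k, g$pool_s, g$pool_p, conv_size)
    cols <- .invert_op(cols, g$pool_k, g$pool_s, g$pool_p, conv_size)
    rows <- .invert_op(rows, g$conv_k, g$conv_s, g$conv_p, in_size)
    cols <- .invert_op(cols, g$conv_k, g$conv_s, g$conv_p, in_size)
  }
  list(rows = rows, cols = cols,
       side = max(diff(rows), diff(cols)) + 1L)
}
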