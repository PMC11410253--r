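# Cross-layer connectivity attribution: which input channels drive or
# inhibit a target unit. Each input channel's contribution is the product of
# (1) the summed weights of the 3x3 convolution filter connecting it to the
# target channel — summation rather than a norm, because rectified inputs
# are non-negative and negative weights can only dampen — and (2) the
# channel's "drive": the maximum response of word-selective input units
# inside the target's effective receptive field over the target's 20-image
# factorial probe set.

#' Per-input-channel summed filter weights
#'
#' @param model a `cornet_model`.
#' @param target_layer block whose convolution input weights are read (e.g.
#'   "IT" for the V4-to-IT filters).
#' @param target_channel output channel of the target unit.
#' @return Numeric vector, one summed 3x3 (or kxk) kernel per input channel
#'   (length 256 for the default V4-to-IT case).
#' @export
filter_weight_sums <- function(model, target_layer, target_channel) {
  blk <- model$blocks[[target_layer]]
  if (is.null(blk)) stop("layer '", target_layer,
                         "' has no convolution weights", call. = FALSE)
  W <- blk$W
  apply(W[, , , target_channel, drop = FALSE], 3, sum)
}

#' Per-channel drive from word-selective input units in the receptive field
#'
#' For each input channel, takes the maximum over the target's 20 probe
#' stimuli and over the word-selective units of that channel lying inside
#' the target unit's effective receptive field on the input layer. Channels
#' with no word-selective unit in the field get drive 0 and are flagged.
#'
#' @param model a `cornet_model`.
#' @param target list with `layer`, `channel`, `row`, `col` of the target
#'   unit.
#' @param input_layer name of the input layer (e.g. "V4").
#' @param input_store `activation_store` holding the input layer's responses
#'   to the target's factorial probe stimuli.
#' @param word_selective logical vector over the input layer's units (flat
#'   indexing as in the store).
#' @return List with `drive` (numeric per channel) and `no_unit_in_rf`
#'   (logical per channel).
#' @export
channel_drive <- function(model, target, input_layer, input_store,
                          word_selective) {
  if (input_store$n_stimuli < 1) stop("empty probe store", call. = FALSE)
  rf <- effective_receptive_field(model, target$layer, target$row,
                                  target$col, input_layer)
  dims <- input_store$dims[[input_layer]]
  acts <- input_store$layers[[input_layer]]
  if (length(word_selective) != ncol(acts))
    stop("word_selective length does not match the store's unit count",
         call. = FALSE)
  n_ch <- dims[3]
  drive <- numeric(n_ch); empty <- logical(n_ch)
  rows <- rf$rows[1]:rf$rows[2]; cols <- rf$cols[1]:rf$cols[2]
  grid <- expand.grid(row = rows, col = cols)
  for (ch in seq_len(n_ch)) {
    idx <- unit_index(dims, ch, grid$row, grid$col)
    idx <- idx[word_selective[idx]]
    if (!length(idx)) { empty[ch] <- TRUE; next }
    drive[ch] <- max(acts[, idx, drop = FALSE])
  }
  list(drive = drive, no_unit_in_rf = empty)
}

#' Connectivity attribution report for one target unit
#'
#' Multiplies summed filter weights by channel drive and ranks input
#' channels into top excitatory (largest positive product) and top
#' inhibitory (most negative product) lists.
#'
#' @inheritParams channel_drive
#' @param k channels reported per sign (default 2).
#' @return A `connectivity_report`: list with `target`, `weight_sums`,
#'   `drive`, `product`, `top_excitatory`, `top_inhibitory`,
#'   `no_unit_in_rf`, `all_drives_zero`.
#' @export
attribute <- function(model, target, input_layer, input_store,
                      word_selective, k = 2L) {
  ws <- filter_weight_sums(model, target$layer, target$channel)
  cd <- channel_drive(model, target, input_layer, input_store,
                      word_selective)
  product <- ws * cd$drive
  all_zero <- all(cd$drive == 0)
  top_exc <- integer(0); top_inh <- integer(0)
  if (!all_zero) {
    pos <- which(product > 0); neg <- which(product < 0)
    top_exc <- pos[order(product[pos], decreasing = TRUE)][
      seq_len(min(k, length(pos)))]
    top_inh <- neg[order(product[neg])][seq_len(min(k, length(neg)))]
  }
  structure(list(target = target, weight_sums = ws, drive = cd$drive,
                 product = product, top_excitatory = top_exc,
                 top_inhibitory = top_inh,
                 no_unit_in_rf = cd$no_unit_in_rf,
                 all_drives_zero = all_zero),
            class = "connectivity_report")
}

#' Spatial-frequency characterization of first-layer filters
#'
#' Computes the 2-D Fourier amplitude spectrum of each first-block kernel
#' (averaged across input channels), finds the radial frequency of the
#' spectral peak, and splits filters into low/high classes at the median
#' peak frequency.
#'
#' @param model a `cornet_model`.
#' @param layer block whose kernels are analysed (default "V1").
#' @return Data.frame: `filter`, `peak_freq` (cycles/pixel, 0 to ~0.71),
#'   `class` ("low"/"high").
#' @export
v1_filter_spectrum <- function(model, layer = "V1") {
  W <- model$blocks[[layer]]$W
  k <- dim(W)[1]
  fr <- (seq_len(k) - 1) / k
  fr[fr > 0.5] <- fr[fr > 0.5] - 1          # signed frequencies
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  nf <- dim(W)[4]
  peak <- numeric(nf)
  for (f in seq_len(nf)) {
    amp <- 0
    for (c in seq_len(dim(W)[3]))
      amp <- amp + Mod(stats::fft(W[, , c, f]))
    peak[f] <- rad[which.max(amp)]
  }
  cls <- ifelse(peak <= stats::median(peak), "low", "high")
  data.frame(filter = seq_len(nf), peak_freq = peak, class = cls)
}
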