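# Synthetic units with planted, symbolically defined tuning.
#
# A synthetic unit's response is a pure function of a stimulus's symbolic
# description (which glyph sits in which slot), never of pixels, so every
# analysis stage can be validated by parameter recovery without a trained
# network. The unit taxonomy mirrors the codes under study: retinotopic
# (letter at a fixed canvas slot), ordinal from word start or end, space
# bigram (letter adjacent to a blank inside a retinotopic window),
# letter-invariant, word-position, and mixtures.

.unit_kinds <- c("retinotopic", "ordinal_start", "ordinal_end",
                 "space_bigram_left", "space_bigram_right",
                 "letter_invariant", "word_position", "mixed")

#' Define a synthetic unit
#'
#' @param kind one of retinotopic, ordinal_start, ordinal_end,
#'   space_bigram_left, space_bigram_right, letter_invariant, word_position,
#'   mixed.
#' @param preferred_letters glyph vector, optionally named weights via
#'   `letter_weights`.
#' @param letter_weights numeric weights (recycled) for `preferred_letters`.
#' @param position_param tuned slot (retinotopic, word_position) or ordinal
#'   index (ordinal kinds; 1 = first from start/end).
#' @param rf retinotopic slot window `c(lo, hi)` (space-bigram kinds).
#' @param tuning_width gaussian falloff width, in slots (retinotopic) or
#'   ordinal steps (ordinal kinds); 0 gives exact indicator tuning.
#' @param gain peak response (> 0; default 10, safely above the default
#'   profile exclusion threshold of 5).
#' @param noise_sd additive gaussian noise, truncated at 0 to mimic rectified
#'   activations.
#' @param components,weights for `kind = "mixed"`: list of synthetic units
#'   and their mixture weights.
#' @return A `synthetic_unit` specification.
#' @export
synthetic_unit <- function(kind, preferred_letters = "O", letter_weights = 1,
                           position_param = 1L, rf = c(1L, 8L),
                           tuning_width = 0, gain = 10, noise_sd = 0,
                           components = NULL, weights = NULL) {
  kind <- match.arg(kind, .unit_kinds)
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  if (kind == "mixed" && (is.null(components) || is.null(weights)))
    stop("mixed units need components and weights", call. = FALSE)
  w <- rep_len(letter_weights, length(preferred_letters))
  names(w) <- toupper(preferred_letters)
  structure(list(kind = kind, letter_weights = w,
                 position_param = position_param, rf = rf,
                 tuning_width = tuning_width, gain = gain,
                 noise_sd = noise_sd, components = components,
                 weights = weights),
            class = "synthetic_unit")
}

#' Slot layout of a glyph string
#'
#' @param x a string (possibly containing `-` blanks) or a character vector
#'   of per-slot glyphs.
#' @param frame_slots pad/crop to this slot count (optional).
#' @return Character vector of glyphs per slot, `-` for blank.
#' @export
parse_slots <- function(x, frame_slots = NULL) {
  slots <- if (length(x) == 1 && is.character(x)) strsplit(x, "")[[1]] else x
  slots[slots == " "] <- "-"
  if (!is.null(frame_slots)) {
    if (length(slots) > frame_slots)
      stop("string longer than frame", call. = FALSE)
    slots <- c(slots, rep("-", frame_slots - length(slots)))
  }
  toupper(slots)
}

#' Slot layout for a plain word
#'
#' @param word alphabetic string.
#' @param frame_slots frame size.
#' @param align "left" (slots 1..L) or "center".
#' @return Per-slot glyph vector.
#' @export
word_layout <- function(word, frame_slots = 8L, align = c("left", "center")) {
  align <- match.arg(align)
  chars <- toupper(strsplit(word, "")[[1]])
  if (length(chars) > frame_slots) stop("word longer than frame", call. = FALSE)
  s <- rep("-", frame_slots)
  off <- if (align == "left") 0L else (frame_slots - length(chars)) %/% 2L
  s[off + seq_along(chars)] <- chars
  s
}

# Noise-free response of a unit to one slot layout.
.respond_clean <- function(spec, slots) {
  if (spec$kind == "mixed") {
    return(sum(vapply(seq_along(spec$components), function(i)
      spec$weights[i] * .respond_clean(spec$components[[i]], slots),
      numeric(1))))
  }
  letter_pos <- which(!slots %in% "-")
  if (!length(letter_pos)) return(0)
  gl <- slots[letter_pos]
  L <- length(letter_pos)
  wts <- spec$letter_weights
  hit <- which(gl %in% names(wts))
  gauss <- function(d) {
    if (spec$tuning_width <= 0) as.numeric(d == 0) else
      exp(-0.5 * (d / spec$tuning_width)^2)
  }
  val <- switch(spec$kind,
    retinotopic = sum(wts[gl[hit]] * gauss(letter_pos[hit] -
                                             spec$position_param)),
    ordinal_start = if (length(hit))
      max(wts[gl[hit]] * gauss(hit - spec$position_param)) else 0,
    ordinal_end = if (length(hit))
      max(wts[gl[hit]] * gauss((L - hit + 1L) - spec$position_param)) else 0,
    space_bigram_left = {
      s <- letter_pos[hit]
      ok <- (s == 1L | slots[pmax(s - 1L, 1L)] == "-") &
        s >= spec$rf[1] & s <= spec$rf[2]
      if (any(ok)) max(wts[gl[hit][ok]]) else 0
    },
    space_bigram_right = {
      s <- letter_pos[hit]
      nxt <- ifelse(s == length(slots), "-", slots[pmin(s + 1L, length(slots))])
      ok <- nxt == "-" & s >= spec$rf[1] & s <= spec$rf[2]
      if (any(ok)) max(wts[gl[hit][ok]]) else 0
    },
    letter_invariant = if (length(hit)) max(wts[gl[hit]]) else 0,
    word_position = as.numeric(letter_pos[1] == spec$position_param))
  spec$gain * val
}

#' Synthetic unit response to stimuli
#'
#' @param spec a [synthetic_unit()].
#' @param stimuli a `probe_design`, a character vector of slot strings, or a
#'   list of per-slot glyph vectors; plain words are laid out with
#'   [word_layout()].
#' @param seed seed for the additive noise stream (ignored at
#'   `noise_sd = 0`).
#' @return Numeric response vector, one value per stimulus.
#' @export
respond <- function(spec, stimuli, seed = 1L) {
  slots_list <- .as_slot_list(stimuli)
  r <- vapply(slots_list, function(s) .respond_clean(spec, s), numeric(1))
  if (spec$noise_sd > 0) {
    rng <- .seeded_rng(seed)
    r <- pmax(0, r + rng$norm(length(r), sd = spec$noise_sd))
  }
  r
}

.as_slot_list <- function(stimuli) {
  if (inherits(stimuli, "probe_design"))
    return(lapply(stimuli$strings, parse_slots))
  if (is.character(stimuli))
    return(lapply(stimuli, function(s) {
      if (grepl("-", s) || s == "") parse_slots(s) else word_layout(s)
    }))
  if (is.list(stimuli)) return(lapply(stimuli, parse_slots))
  stop("stimuli must be a probe design, strings, or slot lists",
       call. = FALSE)
}

#' Generate a synthetic unit population's responses
#'
#' Evaluates every unit on every design, producing response matrices shaped
#' like recorded activations (stimuli x units) plus a ground-truth sidecar
#' table, a drop-in replacement for a trained network in any analysis stage.
#'
#' @param specs list of [synthetic_unit()] objects.
#' @param designs named list of stimulus sets accepted by [respond()].
#' @param seed base seed; each (design, unit) pair gets an independent noise
#'   stream derived from it.
#' @return List with `responses` (named list of n_stimuli x n_units
#'   matrices) and `truth` (data.frame: unit, kind, position_param).
#' @export
generate_population <- function(specs, designs, seed = 1L) {
  responses <- lapply(seq_along(designs), function(di) {
    n_stim <- length(.as_slot_list(designs[[di]]))
    m <- matrix(0, n_stim, length(specs))
    for (u in seq_along(specs))
      m[, u] <- respond(specs[[u]], designs[[di]],
                        seed = .child_seed(seed, paste0(di, "_", u)))
    m
  })
  names(responses) <- names(designs)
  truth <- data.frame(
    unit = seq_along(specs),
    kind = vapply(specs, `[[`, character(1), "kind"),
    position_param = vapply(specs, function(s)
      if (is.null(s$position_param)) NA_real_ else s$position_param,
      numeric(1)))
  list(responses = responses, truth = truth)
}
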