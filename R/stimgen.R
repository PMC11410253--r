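# Stimulus generation: rendered word images, training/test datasets, factorial
# and spaced probe sets, single-letter grids, bigram sets, and a category
# localizer set with procedural non-word categories.
#
# All images are H x W x 3 arrays with values in [0, 1], dark ink on a light
# background (the regime under which early layers develop dark-line
# preferences). Generators are pure functions of their arguments and seed.

#' Apply a case convention to a character string
#'
#' @param text character string.
#' @param case one of "upper", "lower", "mixed" (title case).
#' @return The recased string.
#' @export
apply_case <- function(text, case = c("upper", "lower", "mixed")) {
  case <- match.arg(case)
  switch(case,
    upper = toupper(text),
    lower = tolower(text),
    mixed = paste0(toupper(substr(text, 1, 1)), tolower(substring(text, 2))))
}

# Width in pixels of a proportional-mode rendering (without trailing gap).
.word_px_width <- function(text, font_id, size_pt, case, canvas) {
  shown <- if (identical(case, "asis")) text else apply_case(text, case)
  chars <- strsplit(shown, "")[[1]]
  met <- .glyph_metrics(size_pt, canvas)
  tot <- 0L
  for (ch in chars) {
    tot <- tot + if (ch %in% c("-", " ")) met$advance else
      .glyph_dims(ch, font_id, size_pt, canvas)[["w"]] + met$gap
  }
  tot - met$gap
}

# Largest size (integer pt) in [lo, hi] at which the word fits the canvas
# with at least a 1-pixel margin; NA if none does.
.fit_size <- function(word, font_id, case, size_range, canvas) {
  for (s in seq(floor(size_range[2]), ceiling(size_range[1]), by = -1)) {
    if (.word_px_width(word, font_id, s, case, canvas) <= canvas - 2 &&
        .px_height(s, canvas) <= canvas - 2)
      return(s)
  }
  NA_real_
}

#' Render a word (or slot frame) as an image stimulus
#'
#' Renders `text` as dark glyphs on a light canvas. In proportional mode
#' (`frame_slots = NULL`) glyphs advance continuously and the word is centred
#' at the canvas centre plus `offset`. In slot mode, the canvas carries
#' `frame_slots` equal-width slots centred on the canvas; each character of
#' `text` occupies one slot, and the characters `-` and a literal space are
#' truly empty slots (no ink), as required by probe designs.
#'
#' @param text glyph string; must be non-empty after stripping whitespace
#'   unless it consists of blanks in slot mode.
#' @param font_id one of [orthonet_fonts()].
#' @param size_pt nominal point size (default range 30-70 at a 224 canvas).
#' @param offset integer `c(dx, dy)` pixel offset from the canvas centre
#'   (positive = right/down).
#' @param case case convention applied to `text` ("upper", "lower", "mixed"),
#'   or "asis" to render the string untouched.
#' @param canvas canvas edge in pixels (square canvas).
#' @param frame_slots number of slots in slot mode, or `NULL`.
#' @return An object of class `rendered_stimulus`: a list with elements
#'   `image` (canvas x canvas x 3 array in \[0,1\]), `text`, `font_id`,
#'   `size_pt`, `offset`, `case`.
#' @export
render_word <- function(text, font_id = "sans", size_pt = 50,
                        offset = c(0L, 0L), case = "upper", canvas = 224L,
                        frame_slots = NULL) {
  stopifnot(length(offset) == 2, canvas >= 16)
  slotted <- !is.null(frame_slots)
  if (!nzchar(gsub("[[:space:]-]", "", text)) && !slotted)
    stop("text is empty after stripping", call. = FALSE)
  shown <- if (identical(case, "asis")) text else apply_case(text, case)
  chars <- strsplit(shown, "")[[1]]
  met <- .glyph_metrics(size_pt, canvas)
  ink <- matrix(0, canvas, canvas)  # ink mask; 1 = ink
  cy <- canvas / 2 + offset[2]
  place <- function(bm, x0, y0) {
    h <- nrow(bm); w <- ncol(bm)
    x0 <- as.integer(round(x0)); y0 <- as.integer(round(y0))
    if (y0 < 1 || x0 < 1 || y0 + h - 1 > canvas || x0 + w - 1 > canvas)
      stop("glyph ink exceeds the canvas (offset/size out of admissible range)",
           call. = FALSE)
    sub <- ink[y0:(y0 + h - 1), x0:(x0 + w - 1)]
    sub[bm] <- 1
    ink[y0:(y0 + h - 1), x0:(x0 + w - 1)] <<- sub
  }
  if (slotted) {
    if (length(chars) > frame_slots)
      stop("frame too small: ", length(chars), " characters for ",
           frame_slots, " slots", call. = FALSE)
    chars <- c(chars, rep("-", frame_slots - length(chars)))
    slot_w <- met$advance
    x_left <- canvas / 2 - frame_slots * slot_w / 2 + offset[1]
    for (s in seq_along(chars)) {
      ch <- chars[s]
      if (ch %in% c("-", " ")) next
      g <- .render_glyph(ch, font_id, size_pt, canvas)
      x0 <- x_left + (s - 1) * slot_w + (slot_w - ncol(g$bitmap)) / 2
      y0 <- cy - met$h / 2 + g$drop
      place(g$bitmap, x0 + 1, y0 + 1)
    }
  } else {
    glyphs <- lapply(chars, function(ch) {
      if (ch %in% c("-", " ")) NULL else .render_glyph(ch, font_id, size_pt, canvas)
    })
    widths <- vapply(glyphs, function(g)
      if (is.null(g)) met$advance else ncol(g$bitmap) + met$gap, numeric(1))
    total <- sum(widths) - met$gap
    x <- canvas / 2 - total / 2 + offset[1]
    for (i in seq_along(chars)) {
      g <- glyphs[[i]]
      if (!is.null(g))
        place(g$bitmap, x + 1, cy - met$h / 2 + g$drop + 1)
      x <- x + widths[i]
    }
  }
  image <- array(rep(1 - ink, 3), dim = c(canvas, canvas, 3))
  structure(list(image = image, text = shown, font_id = font_id,
                 size_pt = size_pt, offset = as.integer(round(offset)),
                 case = case),
            class = "rendered_stimulus")
}

#' @export
print.rendered_stimulus <- function(x, ...) {
  cat(sprintf("<rendered_stimulus '%s' font=%s size=%g offset=(%d,%d) %dx%d>\n",
              x$text, x$font_id, x$size_pt, x$offset[1], x$offset[2],
              dim(x$image)[1], dim(x$image)[2]))
  invisible(x)
}

#' Stack rendered stimuli into an image batch array
#'
#' @param stimuli list of `rendered_stimulus` objects (or plain image arrays).
#' @return Array of dimension (H, W, 3, N).
#' @export
as_image_batch <- function(stimuli) {
  imgs <- lapply(stimuli, function(s) if (is.list(s)) s$image else s)
  d <- dim(imgs[[1]])
  out <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

# Default variant parameter ranges at the 224-pixel reference canvas,
# rescaled proportionally for other canvases.
.default_ranges <- function(canvas) {
  s <- canvas / 224
  list(size = c(30, 70), dx = c(-50, 50) * s, dy = c(-30, 30) * s)
}

#' Generate a train/test word dataset manifest
#'
#' Samples variant parameters (font, size, offset, case) for each word:
#' `n_train_per_word` training variants drawn from `fonts_train` and
#' `n_test_per_word` test variants drawn from the disjoint `fonts_test`.
#' Sizes and offsets are sampled uniformly from the admissible part of the
#' configured ranges — the part for which the rendered word stays fully on
#' the canvas, so long words admit a narrower size/offset sub-range. Every
#' sampled value lies inside the configured ranges.
#'
#' @param words character vector of words (3-8 letters recommended).
#' @param n_train_per_word,n_test_per_word variants per word per split.
#' @param fonts_train,fonts_test disjoint font id vectors.
#' @param seed integer RNG seed; identical seeds give identical manifests.
#' @param canvas canvas edge in pixels.
#' @param ranges list with `size`, `dx`, `dy` ranges; defaults scale the
#'   224-canvas ranges proportionally.
#' @param cases case levels sampled per variant.
#' @return A data.frame manifest with one row per stimulus: `word`, `label`,
#'   `split`, `font`, `size_pt`, `dx`, `dy`, `case`.
#' @export
make_training_set <- function(words, n_train_per_word = 1300L,
                              n_test_per_word = 50L,
                              fonts_train = c("sans", "bold"),
                              fonts_test = c("slant", "serif", "backslant"),
                              seed = 1L, canvas = 224L, ranges = NULL,
                              cases = c("upper", "lower")) {
  if (!length(words)) stop("word list is empty", call. = FALSE)
  if (!length(fonts_train) || !length(fonts_test))
    stop("font list is empty", call. = FALSE)
  if (length(intersect(fonts_train, fonts_test)))
    stop("train and test fonts must be disjoint", call. = FALSE)
  if (is.null(ranges)) ranges <- .default_ranges(canvas)
  rng <- .seeded_rng(seed)
  fit_cache <- new.env(parent = emptyenv())
  sample_split <- function(word, label, n, fonts, split) {
    font <- fonts[rng$int(n, length(fonts))]
    case <- cases[rng$int(n, length(cases))]
    size <- numeric(n); dx <- numeric(n); dy <- numeric(n)
    for (i in seq_len(n)) {
      key <- paste(word, font[i], case[i])
      fit <- fit_cache[[key]]
      if (is.null(fit)) {
        fit <- .fit_size(word, font[i], case[i], ranges$size, canvas)
        fit_cache[[key]] <- fit
      }
      if (is.na(fit))
        stop("word '", word, "' cannot fit the canvas at any size in range",
             call. = FALSE)
      size[i] <- min(round(rng$unif(1, ranges$size[1], fit), 1), fit)
      wpx <- .word_px_width(word, font[i], size[i], case[i], canvas)
      hpx <- .px_height(size[i], canvas)
      xmax <- min(ranges$dx[2], (canvas - wpx) / 2 - 1)
      ymax <- min(ranges$dy[2], (canvas - hpx) / 2 - 1)
      dx[i] <- round(rng$unif(1, max(ranges$dx[1], -xmax), xmax))
      dy[i] <- round(rng$unif(1, max(ranges$dy[1], -ymax), ymax))
    }
    data.frame(word = word, label = label, split = split, font = font,
               size_pt = size, dx = dx, dy = dy, case = case,
               stringsAsFactors = FALSE)
  }
  out <- vector("list", 2L * length(words))
  for (w in seq_along(words)) {
    out[[2 * w - 1]] <- sample_split(words[w], w, n_train_per_word,
                                     fonts_train, "train")
    out[[2 * w]] <- sample_split(words[w], w, n_test_per_word,
                                 fonts_test, "test")
  }
  manifest <- do.call(rbind, out)
  attr(manifest, "canvas") <- canvas
  manifest
}

#' Render every row of a dataset manifest
#'
#' @param manifest data.frame from [make_training_set()].
#' @param canvas canvas edge; defaults to the manifest's own canvas attribute.
#' @return Image batch array (H, W, 3, N), rows in manifest order.
#' @export
render_dataset <- function(manifest, canvas = attr(manifest, "canvas")) {
  out <- array(0, dim = c(canvas, canvas, 3, nrow(manifest)))
  for (i in seq_len(nrow(manifest))) {
    st <- render_word(manifest$word[i], manifest$font[i], manifest$size_pt[i],
                      c(manifest$dx[i], manifest$dy[i]), manifest$case[i],
                      canvas)
    out[, , , i] <- st$image
  }
  out
}

# ---- probe designs --------------------------------------------------------

.probe_design <- function(strings, meta, preferred, unpreferred, n_rows,
                          n_cols, frame_slots, spaced, font_id, size_pt,
                          canvas, render) {
  stimuli <- NULL
  if (render)
    stimuli <- lapply(strings, render_word, font_id = font_id,
                      size_pt = size_pt, offset = c(0L, 0L), case = "asis",
                      canvas = canvas, frame_slots = frame_slots)
  structure(list(preferred_letter = preferred, unpreferred_letter = unpreferred,
                 n_rows = n_rows, n_cols = n_cols, frame_slots = frame_slots,
                 spaced = spaced, strings = strings, meta = meta,
                 font_id = font_id, size_pt = size_pt, canvas = canvas,
                 stimuli = stimuli),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("<probe_design %s %dx%d '%s' vs '%s', %d stimuli>\n",
              if (x$spaced) "spaced" else "factorial", x$n_rows, x$n_cols,
              x$preferred_letter, x$unpreferred_letter, length(x$strings)))
  invisible(x)
}

#' Factorial probe design (word position x ordinal position)
#'
#' Builds the 5x4 factorial stimulus matrix: a 4-letter string of the
#' unpreferred letter with a single preferred letter embedded. Row r places
#' the string starting at slot r of an 8-slot frame (absolute word position);
#' column c puts the preferred letter at ordinal position c within the string.
#' Remaining slots are blank (`-`).
#'
#' @param preferred,unpreferred single distinct glyphs.
#' @param frame_slots total slot count (default 8).
#' @param n_rows,word_len rows of the design and string length (defaults 5, 4).
#' @param font_id,size_pt,canvas rendering parameters.
#' @param render if `FALSE`, build strings and metadata only.
#' @return A `probe_design` with `n_rows * n_cols` stimuli in row-major order
#'   and a `meta` data.frame (`row`, `col`, `string`, `pref_slot`).
#' @export
make_factorial_probe <- function(preferred, unpreferred, frame_slots = 8L,
                                 n_rows = 5L, word_len = 4L,
                                 font_id = "sans", size_pt = 50,
                                 canvas = 224L, render = TRUE) {
  if (identical(preferred, unpreferred))
    stop("preferred and unpreferred letters must differ", call. = FALSE)
  if (n_rows + word_len - 1L > frame_slots)
    stop("frame too small for word length plus row range", call. = FALSE)
  grid <- expand.grid(col = seq_len(word_len), row = seq_len(n_rows))
  strings <- character(nrow(grid)); pref_slot <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; c <- grid$col[i]
    s <- rep("-", frame_slots)
    s[r:(r + word_len - 1L)] <- unpreferred
    s[r + c - 1L] <- preferred
    strings[i] <- paste(s, collapse = "")
    pref_slot[i] <- r + c - 1L
  }
  meta <- data.frame(row = grid$row, col = grid$col, string = strings,
                     pref_slot = pref_slot, stringsAsFactors = FALSE)
  .probe_design(strings, meta, preferred, unpreferred, n_rows, word_len,
                frame_slots, FALSE, font_id, size_pt, canvas, render)
}

#' Spaced probe design (blank-separated letters)
#'
#' Builds the 4x3 spaced stimulus matrix: three letters separated by single
#' blank slots (pattern `x-o-x`), occupying five slots of an 8-slot frame.
#' Row r starts the pattern at slot r; column c puts the preferred letter at
#' ordinal position c among the three letters.
#'
#' @inheritParams make_factorial_probe
#' @param n_letters letters per stimulus (default 3).
#' @return A `probe_design` (spaced) with `n_rows * n_letters` stimuli.
#' @export
make_spaced_probe <- function(preferred, unpreferred, frame_slots = 8L,
                              n_rows = 4L, n_letters = 3L,
                              font_id = "sans", size_pt = 50,
                              canvas = 224L, render = TRUE) {
  if (identical(preferred, unpreferred))
    stop("preferred and unpreferred letters must differ", call. = FALSE)
  span <- 2L * n_letters - 1L
  if (n_rows + span - 1L > frame_slots)
    stop("frame too small for spaced pattern plus row range", call. = FALSE)
  grid <- expand.grid(col = seq_len(n_letters), row = seq_len(n_rows))
  strings <- character(nrow(grid)); pref_slot <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; c <- grid$col[i]
    s <- rep("-", frame_slots)
    s[r + 2L * (seq_len(n_letters) - 1L)] <- unpreferred
    s[r + 2L * (c - 1L)] <- preferred
    strings[i] <- paste(s, collapse = "")
    pref_slot[i] <- r + 2L * (c - 1L)
  }
  meta <- data.frame(row = grid$row, col = grid$col, string = strings,
                     pref_slot = pref_slot, stringsAsFactors = FALSE)
  .probe_design(strings, meta, preferred, unpreferred, n_rows, n_letters,
                frame_slots, TRUE, font_id, size_pt, canvas, render)
}

#' Single-letter grid stimuli
#'
#' One stimulus per (letter, slot) pair: the letter alone at each of the
#' `frame_slots` positions. A 26-letter alphabet over 8 slots yields 208
#' stimuli, the tuning table used to find a unit's preferred letter.
#'
#' @param alphabet character vector of glyphs.
#' @inheritParams make_factorial_probe
#' @return List with `stimuli` (or strings if `render = FALSE`) and `meta`
#'   data.frame (`letter`, `slot`, `string`).
#' @export
make_single_letter_grid <- function(alphabet = LETTERS, frame_slots = 8L,
                                    font_id = "sans", size_pt = 50,
                                    canvas = 224L, render = TRUE) {
  if (!length(alphabet)) stop("alphabet is empty", call. = FALSE)
  grid <- expand.grid(slot = seq_len(frame_slots), letter = alphabet,
                      stringsAsFactors = FALSE)
  strings <- vapply(seq_len(nrow(grid)), function(i) {
    s <- rep("-", frame_slots)
    s[grid$slot[i]] <- grid$letter[i]
    paste(s, collapse = "")
  }, character(1))
  meta <- data.frame(letter = grid$letter, slot = grid$slot, string = strings,
                     stringsAsFactors = FALSE)
  stimuli <- NULL
  if (render)
    stimuli <- lapply(strings, render_word, font_id = font_id,
                      size_pt = size_pt, offset = c(0L, 0L), case = "asis",
                      canvas = canvas, frame_slots = frame_slots)
  list(stimuli = stimuli, meta = meta, frame_slots = frame_slots,
       canvas = canvas)
}

#' Bigram stimulus set
#'
#' Renders `n_bigrams` two-glyph strings at the canvas centre, the stimulus
#' set for mean pairwise dissimilarity analyses (49 bigrams give 1176
#' unordered pairs; 25 give 300).
#'
#' @param alphabet glyph pool from which bigrams are drawn.
#' @param n_bigrams number of distinct bigrams (>= 2).
#' @param seed RNG seed for the deterministic draw of bigram identities.
#' @inheritParams make_factorial_probe
#' @return List with `stimuli`, `bigrams` (character vector), `canvas`.
#' @export
make_bigram_set <- function(alphabet = LETTERS, n_bigrams = 49L, seed = 1L,
                            font_id = "sans", size_pt = 50, canvas = 224L,
                            render = TRUE) {
  if (n_bigrams < 2) stop("need at least two bigrams", call. = FALSE)
  all_bg <- as.vector(outer(alphabet, alphabet, paste0))
  all_bg <- all_bg[substr(all_bg, 1, 1) != substr(all_bg, 2, 2)]
  if (n_bigrams > length(all_bg))
    stop("not enough distinct bigrams in the alphabet", call. = FALSE)
  rng <- .seeded_rng(seed)
  bigrams <- all_bg[rng$sample_idx(length(all_bg), n_bigrams)]
  stimuli <- NULL
  if (render)
    stimuli <- lapply(bigrams, render_word, font_id = font_id,
                      size_pt = size_pt, offset = c(0L, 0L), case = "asis",
                      canvas = canvas)
  list(stimuli = stimuli, bigrams = bigrams, canvas = canvas)
}
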