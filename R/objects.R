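# Procedural non-word image categories.
#
# The category localizer contrasts words against faces, houses, bodies and
# tools. Those categories are drawn procedurally (textured blob faces,
# rectilinear house composites, articulated body silhouettes, elongated
# handled tool shapes) rather than taken from photograph datasets: the
# localizer only needs non-word contrast categories with the same dark-ink-
# on-light-background statistics as the word images. Four filler shape
# classes enrich the object-recognition phase of training.

.pixel_grid <- function(canvas) {
  list(x = matrix(rep(seq_len(canvas), each = canvas), canvas, canvas,
                  byrow = TRUE),
       y = matrix(rep(seq_len(canvas), canvas), canvas, canvas))
}

.m_ellipse <- function(g, cx, cy, rx, ry) {
  ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 <= 1
}

.m_ring <- function(g, cx, cy, rx, ry, th = 0.15) {
  v <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2
  v <= 1 & v >= (1 - th)^2
}

.m_rect <- function(g, x0, x1, y0, y1) {
  g$x >= x0 & g$x <= x1 & g$y >= y0 & g$y <= y1
}

.m_seg <- function(g, x0, y0, x1, y1, thick) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- max(vx^2 + vy^2, 1e-9)
  t <- pmin(1, pmax(0, ((g$x - x0) * vx + (g$y - y0) * vy) / len2))
  (g$x - (x0 + t * vx))^2 + (g$y - (y0 + t * vy))^2 <= (thick / 2)^2
}

#' Procedural object categories
#'
#' @return Character vector of available category names. The first four
#'   (face, house, body, tool) are the localizer contrast categories.
#' @export
object_categories <- function() {
  c("face", "house", "body", "tool", "blob", "stripes", "rings", "wedge")
}

# One procedural image; rng is a private RNG stream.
.gen_object <- function(category, canvas, rng) {
  g <- .pixel_grid(canvas)
  img <- matrix(1, canvas, canvas)
  paint <- function(mask, shade) img[mask] <<- pmin(img[mask], shade)
  cx <- canvas / 2 + rng$unif(1, -0.1, 0.1) * canvas
  cy <- canvas / 2 + rng$unif(1, -0.1, 0.1) * canvas
  sc <- rng$unif(1, 0.22, 0.33) * canvas   # characteristic radius
  shade <- function() rng$unif(1, 0, 0.45)
  switch(category,
    face = {
      rx <- sc; ry <- sc * rng$unif(1, 1.1, 1.35)
      paint(.m_ring(g, cx, cy, rx, ry, 0.18), shade())
      er <- rx * rng$unif(1, 0.12, 0.2)
      ex <- rx * rng$unif(1, 0.35, 0.5); ey <- ry * 0.3
      paint(.m_ellipse(g, cx - ex, cy - ey, er, er), shade())
      paint(.m_ellipse(g, cx + ex, cy - ey, er, er), shade())
      paint(.m_seg(g, cx, cy - 0.1 * ry, cx, cy + 0.25 * ry,
                   canvas * 0.015), shade())
      mw <- rx * rng$unif(1, 0.4, 0.7)
      paint(.m_seg(g, cx - mw, cy + 0.55 * ry, cx + mw, cy + 0.55 * ry,
                   canvas * 0.03), shade())
    },
    house = {
      a <- sc * rng$unif(1, 0.9, 1.2); b <- sc * rng$unif(1, 0.7, 1.0)
      hr <- sc * rng$unif(1, 0.5, 0.9)
      th <- canvas * 0.02
      paint(.m_rect(g, cx - a, cx + a, cy - b, cy + b) &
              !.m_rect(g, cx - a + th, cx + a - th, cy - b + th, cy + b - th),
            shade())
      paint(.m_seg(g, cx - a, cy - b, cx, cy - b - hr, th), shade())
      paint(.m_seg(g, cx + a, cy - b, cx, cy - b - hr, th), shade())
      dw <- a * rng$unif(1, 0.2, 0.35)
      paint(.m_rect(g, cx - dw, cx + dw, cy + b - 2.2 * dw, cy + b), shade())
      wx <- cx + rng$unif(1, -0.5, 0.5) * a
      ww <- a * 0.2
      paint(.m_rect(g, wx - ww, wx + ww, cy - b + 1.2 * th, cy - b + 2.5 * ww) &
              !.m_rect(g, wx - ww + th, wx + ww - th, cy - b + 1.2 * th + th,
                       cy - b + 2.5 * ww - th), shade())
    },
    body = {
      hr <- sc * rng$unif(1, 0.25, 0.35)
      top <- cy - sc * 1.1
      paint(.m_ellipse(g, cx, top, hr, hr), shade())
      hip <- cy + sc * rng$unif(1, 0.2, 0.4)
      tw <- canvas * rng$unif(1, 0.03, 0.05)
      paint(.m_seg(g, cx, top + hr, cx, hip, tw * 1.6), shade())
      sh <- top + hr + sc * 0.15
      for (s in c(-1, 1)) {
        aa <- rng$unif(1, 0.3, 1.1)     # arm angle
        paint(.m_seg(g, cx, sh, cx + s * sc * sin(aa), sh + sc * cos(aa), tw),
              shade())
        la <- rng$unif(1, 0.1, 0.5)     # leg angle
        paint(.m_seg(g, cx, hip, cx + s * sc * sin(la), hip + sc * cos(la),
                     tw), shade())
      }
    },
    tool = {
      ang <- rng$unif(1, 0, pi)
      hl <- sc * rng$unif(1, 1.2, 1.6)
      dx <- cos(ang) * hl; dy <- sin(ang) * hl
      tw <- canvas * rng$unif(1, 0.02, 0.04)
      paint(.m_seg(g, cx - dx, cy - dy, cx + dx, cy + dy, tw), shade())
      hr <- sc * rng$unif(1, 0.3, 0.5)
      if (rng$unif(1) < 0.5) {
        paint(.m_ellipse(g, cx + dx, cy + dy, hr, hr * 0.6), shade())
      } else {
        px <- -sin(ang) * hr; py <- cos(ang) * hr
        paint(.m_seg(g, cx + dx - px, cy + dy - py, cx + dx + px, cy + dy + py,
                     tw * 3), shade())
      }
    },
    blob = {
      v <- matrix(0, canvas, canvas)
      for (i in seq_len(4)) {
        bx <- cx + rng$unif(1, -0.5, 0.5) * sc
        by <- cy + rng$unif(1, -0.5, 0.5) * sc
        br <- sc * rng$unif(1, 0.3, 0.6)
        v <- v + exp(-(((g$x - bx)^2 + (g$y - by)^2) / (2 * br^2)))
      }
      paint(v > 0.8, shade())
    },
    stripes = {
      ang <- rng$unif(1, 0, pi)
      freq <- rng$unif(1, 2, 5) * 2 * pi / canvas
      ph <- rng$unif(1, 0, 2 * pi)
      wave <- sin((g$x * cos(ang) + g$y * sin(ang)) * freq + ph) > 0.2
      paint(wave & .m_ellipse(g, cx, cy, sc * 1.3, sc * 1.3), shade())
    },
    rings = {
      n <- 2 + rng$int(1, 3)
      for (i in seq_len(n))
        paint(.m_ring(g, cx, cy, sc * i / n, sc * i / n, 0.25 / i), shade())
    },
    wedge = {
      n <- 3 + rng$int(1, 3)
      ang0 <- rng$unif(1, 0, 2 * pi)
      pts <- vapply(seq_len(n), function(i) {
        a <- ang0 + 2 * pi * i / n + rng$unif(1, -0.2, 0.2)
        r <- sc * rng$unif(1, 0.6, 1.2)
        c(cx + r * cos(a), cy + r * sin(a))
      }, numeric(2))
      th <- canvas * 0.02
      for (i in seq_len(n)) {
        j <- i %% n + 1
        paint(.m_seg(g, pts[1, i], pts[2, i], pts[1, j], pts[2, j], th),
              shade())
      }
    },
    stop("unknown object category '", category, "'", call. = FALSE))
  array(rep(img, 3), dim = c(canvas, canvas, 3))
}

#' Generate images for one procedural object category
#'
#' @param category one of [object_categories()].
#' @param n number of images.
#' @param canvas canvas edge in pixels.
#' @param seed RNG seed.
#' @return List of (canvas, canvas, 3) image arrays.
#' @export
make_object_images <- function(category, n, canvas = 224L, seed = 1L) {
  rng <- .seeded_rng(.child_seed(seed, category))
  lapply(seq_len(n), function(i) .gen_object(category, canvas, rng))
}

#' Category localizer stimulus set
#'
#' Builds the word-versus-categories localizer set: `n_words` word images
#' with random variant parameters plus `n_per_category` images for each
#' non-word category (default faces, houses, bodies, tools), each labelled.
#'
#' @param words word list to sample from.
#' @param n_words number of word stimuli (default 400).
#' @param n_per_category images per non-word category (default 100).
#' @param categories non-word category names.
#' @param seed RNG seed; identical seeds give identical sets.
#' @param canvas canvas edge in pixels.
#' @param fonts fonts used for the word stimuli.
#' @param ranges variant parameter ranges as in [make_training_set()].
#' @param cases case levels for word stimuli.
#' @return List with `images` (list of arrays), `labels` (character vector,
#'   "word" or the category name) and `meta` (word variant manifest rows for
#'   the word stimuli).
#' @export
make_localizer_set <- function(words, n_words = 400L, n_per_category = 100L,
                               categories = c("face", "house", "body", "tool"),
                               seed = 1L, canvas = 224L,
                               fonts = c("sans", "bold"), ranges = NULL,
                               cases = c("upper", "lower")) {
  if (is.null(ranges)) ranges <- .default_ranges(canvas)
  rng <- .seeded_rng(.child_seed(seed, "locwords"))
  word <- words[rng$int(n_words, length(words))]
  font <- fonts[rng$int(n_words, length(fonts))]
  case <- cases[rng$int(n_words, length(cases))]
  images <- vector("list", n_words)
  meta <- data.frame(word = word, font = font, size_pt = 0,
                     dx = 0, dy = 0, case = case, stringsAsFactors = FALSE)
  for (i in seq_len(n_words)) {
    fit <- .fit_size(word[i], font[i], case[i], ranges$size, canvas)
    if (is.na(fit))
      stop("word '", word[i], "' cannot fit the canvas", call. = FALSE)
    size <- min(round(rng$unif(1, ranges$size[1], fit), 1), fit)
    meta$size_pt[i] <- size
    wpx <- .word_px_width(word[i], font[i], size, case[i], canvas)
    hpx <- .px_height(size, canvas)
    xmax <- min(ranges$dx[2], (canvas - wpx) / 2 - 1)
    ymax <- min(ranges$dy[2], (canvas - hpx) / 2 - 1)
    meta$dx[i] <- round(rng$unif(1, max(ranges$dx[1], -xmax), xmax))
    meta$dy[i] <- round(rng$unif(1, max(ranges$dy[1], -ymax), ymax))
    images[[i]] <- render_word(word[i], font[i], size,
                               c(meta$dx[i], meta$dy[i]), case[i],
                               canvas)$image
  }
  labels <- rep("word", n_words)
  for (cat in categories) {
    images <- c(images, make_object_images(cat, n_per_category, canvas,
                                           seed = .child_seed(seed, cat)))
    labels <- c(labels, rep(cat, n_per_category))
  }
  list(images = images, labels = labels, meta = meta)
}
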