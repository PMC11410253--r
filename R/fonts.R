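# Procedural bitmap fonts.
#
# Glyphs are defined in code as 5x7 bitmaps and scaled to the requested pixel
# height by nearest-neighbour resampling. Five font variants are derived
# deterministically from the same base shapes: "sans" (base), "bold"
# (horizontal dilation), "slant" / "backslant" (sheared), and "serif"
# (thickened terminals). Two variants ("sans", "bold") are reserved for
# training sets and three for test sets, mirroring the train/test font split
# used for synthetic word datasets. Everything is a pure function of its
# arguments, so rendered images are bit-identical across calls and platforms.

.glyph_rows <- list(
  A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  D = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  G = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  I = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  J = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  K = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  M = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  Q = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  V = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  W = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  X = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  Y = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  Z = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####")
)

.font_ids <- c("sans", "bold", "slant", "serif", "backslant")
.font_shear <- c(sans = 0, bold = 0, slant = 0.15, serif = 0,
                 backslant = -0.15)

#' Registered procedural fonts
#'
#' @return Character vector of available font identifiers. The first two
#'   ("sans", "bold") are the default training fonts; the remaining three are
#'   the default test fonts.
#' @export
orthonet_fonts <- function() .font_ids

.base_glyph <- function(ch) {
  rows <- .glyph_rows[[toupper(ch)]]
  if (is.null(rows))
    stop("glyph '", ch, "' is not present in the font", call. = FALSE)
  m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
  storage.mode(m) <- "logical"
  m
}

# Apply the font's deterministic shape transform at base (5x7) resolution.
.font_glyph <- function(ch, font_id) {
  m <- .base_glyph(ch)
  if (font_id == "bold") {
    m <- m | cbind(FALSE, m[, -ncol(m), drop = FALSE])
  } else if (font_id == "serif") {
    dil <- function(v) v | c(FALSE, v[-length(v)]) | c(v[-1], FALSE)
    m[1, ] <- dil(m[1, ])
    m[nrow(m), ] <- dil(m[nrow(m), ])
  }
  m
}

# Nearest-neighbour scale of a logical bitmap to h x w pixels.
.scale_bitmap <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(h) / h * nrow(m))))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(w) / w * ncol(m))))
  m[ri, ci, drop = FALSE]
}

# Horizontal shear: row i (1 = top) is shifted right by shear*(h-i) pixels
# (left for negative shear). Returns a wider bitmap.
.shear_bitmap <- function(m, shear) {
  if (shear == 0) return(m)
  h <- nrow(m)
  shift <- round(abs(shear) * (h - seq_len(h)))
  if (shear < 0) shift <- max(shift) - shift
  out <- matrix(FALSE, h, ncol(m) + max(shift))
  for (i in seq_len(h))
    out[i, shift[i] + seq_len(ncol(m))] <- m[i, ]
  out
}

# Pixel metrics for a font at a given point size and canvas. The point->pixel
# scale is chosen so that the longest supported word frame (8 letters) at the
# maximum default size fits a 224-pixel canvas; all sizes scale linearly and
# the whole geometry scales with the canvas edge.
.px_height <- function(size_pt, canvas) {
  max(5L, as.integer(round(size_pt * 0.55 * canvas / 224)))
}

.glyph_metrics <- function(size_pt, canvas) {
  h <- .px_height(size_pt, canvas)
  w <- max(3L, as.integer(round(h * 5 / 7)))
  gap <- max(1L, as.integer(round(h / 7)))
  list(h = h, w = w, gap = gap, advance = w + gap)
}

# Pixel height/width of one glyph without rendering it; must agree exactly
# with the bitmap produced by .render_glyph (including shear widening).
.glyph_dims <- function(ch, font_id, size_pt, canvas) {
  met <- .glyph_metrics(size_pt, canvas)
  lower <- ch %in% letters
  h <- if (lower) max(4L, as.integer(round(met$h * 0.72))) else met$h
  w <- max(3L, as.integer(round(h * 5 / 7)))
  sh <- .font_shear[[font_id]]
  if (sh != 0) w <- w + as.integer(round(abs(sh) * (h - 1)))
  c(h = h, w = w)
}

# Render one glyph to a logical ink bitmap at the font's metrics.
# Lower-case characters reuse the upper-case shapes at reduced height
# (a small-caps simplification), baseline-aligned.
.render_glyph <- function(ch, font_id, size_pt, canvas) {
  if (!font_id %in% .font_ids)
    stop("unknown font '", font_id, "'", call. = FALSE)
  met <- .glyph_metrics(size_pt, canvas)
  lower <- ch %in% letters
  h <- if (lower) max(4L, as.integer(round(met$h * 0.72))) else met$h
  w <- max(3L, as.integer(round(h * 5 / 7)))
  m <- .scale_bitmap(.font_glyph(ch, font_id), h, w)
  m <- .shear_bitmap(m, .font_shear[[font_id]])
  list(bitmap = m, drop = met$h - h)  # drop: baseline alignment offset
}
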