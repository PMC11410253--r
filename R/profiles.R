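# Factorial response profiles: build per-unit response matrices over a probe
# design, binarize with a relative threshold, and categorize the support
# pattern as word-position (row structure), ordinal (column structure),
# retinotopic (diagonal structure) or mixed; reclassify ordinal candidates
# with the spaced design to separate space-bigram coding from genuine
# ordinal coding.

#' Build a unit's factorial response matrix
#'
#' @param responses numeric vector of the unit's responses, ordered as the
#'   design's `meta` rows.
#' @param design a `probe_design`.
#' @return A `response_matrix`: list with `raw` (n_rows x n_cols), the
#'   design reference, and empty binarization slots.
#' @export
build_response_matrix <- function(responses, design) {
  if (length(responses) != nrow(design$meta))
    stop("missing stimulus responses: expected ", nrow(design$meta),
         ", got ", length(responses), call. = FALSE)
  raw <- matrix(NA_real_, design$n_rows, design$n_cols)
  raw[cbind(design$meta$row, design$meta$col)] <- responses
  structure(list(raw = raw, design = design, binary = NULL, excluded = NA,
                 category = NA_character_),
            class = "response_matrix")
}

#' Binarize a response matrix
#'
#' Cells at or above `min + frac * (max - min)` become 1. Units whose
#' maximum raw response is below `exclusion` are flagged excluded (as are
#' constant matrices, which have no range to threshold). The threshold is
#' relative, so any positive affine rescaling of the raw matrix (with the
#' maximum still above `exclusion`) yields the same binary pattern.
#'
#' @param raw numeric response matrix (or a `response_matrix`).
#' @param frac threshold fraction of the range (default 0.30).
#' @param exclusion exclusion threshold on the raw maximum (default 5, in
#'   the activation units of the full-scale network; scaled networks need a
#'   scale-appropriate value).
#' @return List with `binary` (0/1 matrix), `excluded`, `threshold`,
#'   `max_raw`.
#' @export
binarize <- function(raw, frac = 0.30, exclusion = 5) {
  if (inherits(raw, "response_matrix")) raw <- raw$raw
  if (!length(raw)) stop("empty response matrix", call. = FALSE)
  mx <- max(raw); mn <- min(raw)
  thr <- mn + frac * (mx - mn)
  excluded <- mx < exclusion || mx == mn
  list(binary = (raw >= thr) * 1L, excluded = excluded, threshold = thr,
       max_raw = mx)
}

# Vectorized decision rule on directional run statistics (`stats`: matrix or
# named vector from cpp_run_stats / cpp_run_stats_all5x4). A direction claims
# the pattern when (a) its longest run has at least `min_run` consecutive
# active cells, (b) at most `max_stray` active cells fall outside runs of
# that length ("violations" — tolerates banded support such as a broadly
# tuned retinotopic diagonal, while rejecting scattered patterns), and
# (c) the active cells do not occupy every line of that direction (a fully
# covered matrix carries no positional information). Priority: column
# (ordinal) > diagonal (retinotopic) > row (word position); else mixed.
.classify_from_runs <- function(stats, n_rows, n_cols, min_run = 3L,
                                max_stray = 1L) {
  if (is.null(dim(stats))) stats <- matrix(stats, 1,
                                           dimnames = list(NULL,
                                                           names(stats)))
  valid <- function(d, total)
    stats[, paste0(d, "_run")] >= min_run &
      stats[, paste0(d, "_viol")] <= max_stray &
      stats[, paste0(d, "_lines")] < total
  out <- rep("mixed", nrow(stats))
  out[valid("row", n_rows)] <- "word_position"
  out[valid("diag", n_rows + n_cols - 1L) |
        valid("anti", n_rows + n_cols - 1L)] <- "retinotopic"
  out[valid("col", n_cols)] <- "ordinal"
  out[stats[, "n_active"] == 0L] <- "mixed"
  out
}

#' Categorize a binarized response profile
#'
#' Counts consecutive active cells along rows, columns, diagonals and
#' reverse diagonals and assigns: ordinal (column-structured support: the
#' unit responds at a fixed ordinal position across word positions),
#' retinotopic (diagonal support: a fixed canvas slot, possibly a band for
#' broad tuning), word_position (row support: a fixed word position across
#' ordinal positions), or mixed. A direction claims the pattern when its
#' longest run has >= `min_run` cells, at most `max_stray` active cells lie
#' outside runs of that length, and the support does not cover every line
#' of the direction; ties resolve column > diagonal > row.
#'
#' @param binary 0/1 matrix from [binarize()].
#' @param min_run minimum run length for a structured claim (default 3).
#' @param max_stray tolerated active cells outside long runs (default 1).
#' @return List with `category`, the run statistics, `empty_support`, and
#'   `preferred` (1-based index of the best line for the claimed direction:
#'   column for ordinal, row for word_position, NA otherwise).
#' @export
categorize <- function(binary, min_run = 3L, max_stray = 1L) {
  b <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  st <- cpp_run_stats(b, min_run)
  cat_ <- .classify_from_runs(st, nrow(b), ncol(b), min_run, max_stray)
  preferred <- NA_integer_
  if (cat_ == "ordinal") preferred <- which.max(colSums(b))
  if (cat_ == "word_position") preferred <- which.max(rowSums(b))
  list(category = cat_, runs = st, empty_support = st[["n_active"]] == 0L,
       preferred = preferred)
}

#' Full profile classification of one unit
#'
#' Convenience wrapper: response matrix, binarization and categorization in
#' one step.
#'
#' @inheritParams build_response_matrix
#' @inheritParams binarize
#' @inheritParams categorize
#' @return List with `raw`, `binary`, `excluded`, `category` ("excluded"
#'   when the unit fails the exclusion criterion), `preferred`.
#' @export
classify_profile <- function(responses, design, frac = 0.30, exclusion = 5,
                             min_run = 3L, max_stray = 1L) {
  rm_ <- build_response_matrix(responses, design)
  bz <- binarize(rm_$raw, frac, exclusion)
  if (bz$excluded)
    return(list(raw = rm_$raw, binary = bz$binary, excluded = TRUE,
                category = "excluded", preferred = NA_integer_))
  ct <- categorize(bz$binary, min_run, max_stray)
  list(raw = rm_$raw, binary = bz$binary, excluded = FALSE,
       category = ct$category, preferred = ct$preferred, runs = ct$runs)
}

#' Per-layer category proportions
#'
#' @param categories_by_layer data.frame with `layer` and `category`
#'   columns (category may include "excluded"), or a named list of category
#'   vectors.
#' @return Data.frame: `layer`, `category`, `n`, `percent` (percentages over
#'   non-excluded units within the layer; excluded units are reported as a
#'   separate row with `percent = NA`).
#' @export
layer_summary <- function(categories_by_layer) {
  if (is.data.frame(categories_by_layer)) {
    layers <- unique(categories_by_layer$layer)
    get_cats <- function(ly)
      categories_by_layer$category[categories_by_layer$layer == ly]
  } else {
    layers <- names(categories_by_layer)
    get_cats <- function(ly) categories_by_layer[[ly]]
  }
  cats <- c("word_position", "ordinal", "retinotopic", "mixed")
  rows <- lapply(layers, function(ly) {
    v <- get_cats(ly)
    n_ok <- sum(v != "excluded")
    r <- data.frame(layer = ly, category = c(cats, "excluded"),
                    n = c(vapply(cats, function(cc) sum(v == cc), integer(1)),
                          sum(v == "excluded")))
    r$percent <- c(if (n_ok) 100 * r$n[seq_along(cats)] / n_ok else
      rep(0, length(cats)), NA)
    r
  })
  do.call(rbind, rows)
}

#' Reclassify an ordinal candidate with the spaced design
#'
#' In the spaced design every letter is flanked by blanks, so a unit that
#' truly encodes ordinal position keeps responding in a fixed ordinal column,
#' while a space-bigram unit (tuned to its letter next to a blank inside a
#' retinotopic window) follows the letter's canvas slot across the matrix —
#' a drifting, slot-consistent support. Units not categorized ordinal on the
#' unspaced design, and excluded spaced matrices, return "other".
#'
#' @param unspaced_category category from the factorial (unspaced) design.
#' @param spaced profile of the spaced design: a list with `binary` and
#'   `excluded` (from [classify_profile()] or [binarize()]).
#' @param design the spaced `probe_design` (provides the preferred letter's
#'   slot per cell).
#' @param slot_tol tolerated spread of the preferred letter's slot across
#'   active cells for a space-bigram claim (default 3, roughly the width of
#'   a mid-layer retinotopic window).
#' @return One of "space_bigram", "ordinal", "other".
#' @export
spaced_reclassify <- function(unspaced_category, spaced, design,
                              slot_tol = 3L) {
  if (!identical(unspaced_category, "ordinal")) return("other")
  if (isTRUE(spaced$excluded)) return("other")
  b <- spaced$binary
  act <- which(b != 0, arr.ind = TRUE)
  if (nrow(act) < 2) return("other")
  cols <- unique(act[, 2])
  if (length(cols) == 1) return("ordinal")
  slots <- design$meta$pref_slot[match(paste(act[, 1], act[, 2]),
                                       paste(design$meta$row,
                                             design$meta$col))]
  if (diff(range(slots)) <= slot_tol) return("space_bigram")
  "other"
}
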