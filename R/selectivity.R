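# Word-selective unit identification (category localizer) and per-unit
# letter tuning.

#' Identify word-selective units
#'
#' A unit is word selective when its mean response to word stimuli exceeds
#' its mean response to every non-word category (faces, houses, bodies,
#' tools) by `k_sd` of that category's across-stimulus standard deviation —
#' the network analogue of an fMRI localizer contrast. Responses are raw
#' post-rectification activations.
#'
#' @param activations_words n_word_stimuli x n_units response matrix.
#' @param activations_categories named list of n_stimuli x n_units matrices,
#'   one per non-word category (>= 2 stimuli each).
#' @param k_sd threshold multiplier (default 3).
#' @return Data.frame with one row per unit: `unit`, `mean_word`,
#'   `mean_<cat>` / `sd_<cat>` per category, and logical `selective`.
#' @export
find_word_selective <- function(activations_words, activations_categories,
                                k_sd = 3) {
  nu <- ncol(activations_words)
  for (nm in names(activations_categories)) {
    m <- activations_categories[[nm]]
    if (ncol(m) != nu)
      stop("unit sets differ between word store and category '", nm, "'",
           call. = FALSE)
    if (nrow(m) < 2)
      stop("category '", nm, "' needs >= 2 stimuli", call. = FALSE)
  }
  out <- data.frame(unit = seq_len(nu),
                    mean_word = colMeans(activations_words))
  selective <- rep(TRUE, nu)
  for (nm in names(activations_categories)) {
    m <- activations_categories[[nm]]
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    out[[paste0("mean_", nm)]] <- mu
    out[[paste0("sd_", nm)]] <- sdv
    selective <- selective & (out$mean_word > mu + k_sd * sdv)
  }
  out$selective <- selective
  attr(out, "k_sd") <- k_sd
  out
}

#' Letter tuning from a single-letter grid
#'
#' Reshapes a unit's responses to the letter x slot grid (26 x 8 by default),
#' takes the maximum across slots per letter, and reports the most and least
#' preferred letter.
#'
#' @param responses numeric vector over the grid stimuli.
#' @param meta the grid's `meta` data.frame (`letter`, `slot`) from
#'   [make_single_letter_grid()].
#' @return List with `table` (letters x slots matrix), `per_letter_max`,
#'   `best_letter`, `worst_letter`.
#' @export
letter_tuning <- function(responses, meta) {
  letters_u <- unique(meta$letter)
  slots_u <- sort(unique(meta$slot))
  if (length(responses) != nrow(meta))
    stop("responses/meta length mismatch", call. = FALSE)
  full <- expand.grid(slot = slots_u, letter = letters_u,
                      stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$letter, full$slot),
                     paste(meta$letter, meta$slot))
  if (length(missing))
    stop("missing (letter, slot) entries: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  tab <- matrix(NA_real_, length(letters_u), length(slots_u),
                dimnames = list(letters_u, slots_u))
  tab[cbind(match(meta$letter, letters_u), match(meta$slot, slots_u))] <-
    responses
  plm <- apply(tab, 1, max)
  list(table = tab, per_letter_max = plm,
       best_letter = letters_u[which.max(plm)],
       worst_letter = letters_u[which.min(plm)])
}

#' Per-layer counts of selective units
#'
#' @param results named list (by layer) of [find_word_selective()] results,
#'   or a single combined data.frame with a `layer` column.
#' @return Data.frame: `layer`, `n_selective`, `n_total`, `percent`.
#' @export
count_selective_by_layer <- function(results) {
  if (is.data.frame(results))
    results <- split(results, results$layer)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(layer = nm, n_selective = sum(r$selective),
               n_total = nrow(r),
               percent = if (nrow(r)) 100 * sum(r$selective) / nrow(r) else 0)
  })
  do.call(rbind, rows)
}
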