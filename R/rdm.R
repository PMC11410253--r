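# Representational dissimilarity: correlation distance d = 1 - r between
# vectorized activation patterns, mean pairwise dissimilarity over a
# stimulus set, and literate-vs-illiterate comparisons.

#' Correlation distance between two activation vectors
#'
#' @param a,b numeric vectors of equal length >= 2 with nonzero variance.
#' @return `d = 1 - r` with r the Pearson correlation; d lies in \[0, 2\].
#' @export
dissimilarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("vectors must have equal length >= 2", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance activation vector", call. = FALSE)
  1 - stats::cor(a, b)
}

#' Mean pairwise dissimilarity over a stimulus set
#'
#' Vectorizes each stimulus's activations and computes `1 - r` for every
#' unordered stimulus pair (49 stimuli give C(49,2) = 1176 pairs). Stimuli
#' with zero-variance activation vectors are dropped with a warning.
#'
#' @param store an `activation_store`, or a plain n_stimuli x n_units
#'   matrix.
#' @param layer layer name when `store` is an activation store.
#' @return A `dissimilarity_result`: list with `layer`, `pair_values`
#'   (named by "i:j" stimulus pairs), `mean_d`, `n_pairs`, `n_dropped`.
#' @export
mean_pairwise <- function(store, layer = NULL) {
  m <- if (inherits(store, "activation_store")) store$layers[[layer]] else
    store
  if (is.null(m)) stop("layer '", layer, "' not in store", call. = FALSE)
  ok <- apply(m, 1, stats::sd) > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance stimulus vector(s) dropped")
  keep <- which(ok)
  if (length(keep) < 2)
    stop("fewer than 2 valid stimuli", call. = FALSE)
  r <- stats::cor(t(m[keep, , drop = FALSE]))
  d <- 1 - r[lower.tri(r)]
  pr <- which(lower.tri(r), arr.ind = TRUE)
  names(d) <- paste0(keep[pr[, 2]], ":", keep[pr[, 1]])
  structure(list(layer = layer, pair_values = d, mean_d = mean(d),
                 n_pairs = length(d), n_dropped = sum(!ok)),
            class = "dissimilarity_result")
}

#' Compare pairwise dissimilarities between two networks
#'
#' Matched-pair comparison of the same stimulus set's dissimilarities under
#' two networks (e.g. literate vs illiterate), per layer: mean difference, a
#' paired two-sided t-test, and optionally a sign-flip permutation test.
#'
#' @param results_a,results_b named lists (by layer) of
#'   `dissimilarity_result` objects over the same stimulus set, or single
#'   results.
#' @param n_perm permutation count for the sign-flip test (0 to skip).
#' @param seed permutation seed.
#' @return Data.frame: `layer`, `mean_a`, `mean_b`, `mean_diff` (a - b),
#'   `t`, `p`, and `p_perm` when requested.
#' @export
compare_networks <- function(results_a, results_b, n_perm = 0L, seed = 1L) {
  if (inherits(results_a, "dissimilarity_result"))
    results_a <- list(results_a)
  if (inherits(results_b, "dissimilarity_result"))
    results_b <- list(results_b)
  if (length(results_a) != length(results_b))
    stop("layer sets differ", call. = FALSE)
  rng <- if (n_perm > 0) .seeded_rng(seed) else NULL
  rows <- lapply(seq_along(results_a), function(i) {
    ra <- results_a[[i]]; rb <- results_b[[i]]
    if (ra$n_pairs != rb$n_pairs ||
        !identical(names(ra$pair_values), names(rb$pair_values)))
      stop("pair sets differ between networks", call. = FALSE)
    dd <- ra$pair_values - rb$pair_values
    if (stats::sd(dd) == 0) {
      tt <- list(statistic = NA_real_, p.value = 1)
    } else {
      tt <- stats::t.test(dd)
    }
    row <- data.frame(layer = if (is.null(ra$layer)) as.character(i) else
      ra$layer, mean_a = ra$mean_d, mean_b = rb$mean_d,
      mean_diff = mean(dd), t = unname(tt$statistic), p = tt$p.value)
    if (n_perm > 0) {
      obs <- mean(dd)
      flips <- matrix(rng$unif(n_perm * length(dd)) < 0.5, n_perm)
      null <- apply(flips, 1, function(f) mean(ifelse(f, -dd, dd)))
      row$p_perm <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    }
    row
  })
  do.call(rbind, rows)
}
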