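# Letter x position encoding models.
#
# A unit's responses Y to a word list are regressed on a binary design
# matrix X with one feature per (letter, slot) pair — 26 letters x 8 slots =
# 208 features — via cross-validated lasso (Y = Xb). Three position schemes
# assign word letters to the 8 slots: left-aligned, word-centred, and
# edge-aligned (initial letters indexed from the word's start, final letters
# from its end). All three use identical feature counts, so their
# cross-validated prediction correlations are directly comparable.

.schemes <- c("left_aligned", "word_centered", "edge_aligned")

# Slot assignment for a word of length L under a scheme.
.scheme_slots <- function(L, scheme, frame_slots = 8L) {
  switch(scheme,
    left_aligned = seq_len(L),
    word_centered = (frame_slots - L) %/% 2L + seq_len(L),
    edge_aligned = {
      nl <- ceiling(L / 2)
      c(seq_len(nl), frame_slots - (L - nl) + seq_len(L - nl) - 0L)
    })
}

#' Build a letter-by-position design matrix
#'
#' @param words character vector of alphabetic words, 3 to `frame_slots`
#'   letters (case-folded to a fixed a..z alphabet order).
#' @param scheme "left_aligned", "word_centered" or "edge_aligned".
#' @param frame_slots number of letter slots (default 8).
#' @param alphabet alphabet defining the feature order; feature index of
#'   (letter, slot) is `nletters * (slot - 1) + rank(letter)`.
#' @return A `design_matrix` object: binary `X` (words x features) with
#'   columns named `<letter><slot>`, plus `scheme` and `words`.
#' @export
build_design_matrix <- function(words, scheme = .schemes, frame_slots = 8L,
                                alphabet = letters) {
  scheme <- match.arg(scheme)
  words <- tolower(words)
  L <- nchar(words)
  if (any(L < 1 | L > frame_slots))
    stop("word longer than the ", frame_slots, "-slot frame: ",
         words[which(L > frame_slots)[1]], call. = FALSE)
  if (any(!grepl("^[a-z]+$", words)))
    stop("words must be alphabetic", call. = FALSE)
  na <- length(alphabet)
  X <- matrix(0L, length(words), na * frame_slots,
              dimnames = list(words, paste0(rep(alphabet, frame_slots),
                                            rep(seq_len(frame_slots),
                                                each = na))))
  for (i in seq_along(words)) {
    chars <- strsplit(words[i], "")[[1]]
    slots <- .scheme_slots(L[i], scheme, frame_slots)
    X[i, na * (slots - 1L) + match(chars, alphabet)] <- 1L
  }
  structure(list(X = X, scheme = scheme, words = words,
                 frame_slots = frame_slots, alphabet = alphabet),
            class = "design_matrix")
}

#' Fit a cross-validated lasso encoding model
#'
#' Solves Y = Xb by L1-regularized regression with the penalty chosen by
#' internal cross-validation. The reported fit quality `cv_r` is the Pearson
#' correlation between out-of-fold predictions (at the CV-optimal penalty)
#' and the observed responses.
#'
#' @param Y numeric response vector (one unit's responses across words).
#' @param X a `design_matrix` or a plain numeric matrix with `length(Y)`
#'   rows.
#' @param cv_folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return An `encoding_fit`: list with `b` (named coefficient vector,
#'   intercept excluded), `intercept`, `cv_r`, `lambda`, `degenerate`
#'   (TRUE for constant Y, where `cv_r` is reported as 0), `scheme`.
#' @export
fit_encoding <- function(Y, X, cv_folds = 5L, seed = 1L) {
  scheme <- if (inherits(X, "design_matrix")) X$scheme else NA_character_
  Xm <- if (inherits(X, "design_matrix")) X$X else X
  if (length(Y) != nrow(Xm)) stop("length(Y) != nrow(X)", call. = FALSE)
  if (stats::sd(Y) == 0) {
    return(structure(list(b = stats::setNames(numeric(ncol(Xm)),
                                              colnames(Xm)),
                          intercept = Y[1], cv_r = 0, lambda = NA_real_,
                          degenerate = TRUE, scheme = scheme),
                     class = "encoding_fit"))
  }
  rng <- .seeded_rng(seed)
  foldid <- rng$perm(length(Y)) %% cv_folds + 1L
  cv <- glmnet::cv.glmnet(Xm, Y, alpha = 1, foldid = foldid, keep = TRUE,
                          nlambda = 50)
  ilam <- which.min(cv$cvm)
  pred_oof <- cv$fit.preval[, ilam]
  cv_r <- if (stats::sd(pred_oof) == 0) 0 else stats::cor(pred_oof, Y)
  cf <- as.numeric(stats::coef(cv, s = cv$lambda[ilam]))
  structure(list(b = stats::setNames(cf[-1], colnames(Xm)),
                 intercept = cf[1], cv_r = cv_r, lambda = cv$lambda[ilam],
                 degenerate = FALSE, scheme = scheme),
            class = "encoding_fit")
}

#' Compare position schemes for a set of units
#'
#' Fits the encoding model under each scheme with an identical regression
#' protocol (same folds, same penalty path policy) and reports per-unit
#' cross-validated correlations and the winning scheme. Schemes whose best
#' and second-best `cv_r` differ by less than `tie_tol` are flagged as tied (default 0.05).
#'
#' @param unit_responses n_words x n_units matrix (or a vector for one
#'   unit).
#' @param words the word list (rows of `unit_responses`).
#' @param schemes schemes to compare (>= 2).
#' @param cv_folds,seed passed to [fit_encoding()]; the fold assignment is
#'   shared across schemes.
#' @param tie_tol tie threshold on cv_r.
#' @return Data.frame: `unit`, one `cv_r_<scheme>` column per scheme,
#'   `winner`, `tie`.
#' @export
compare_schemes <- function(unit_responses, words, schemes = .schemes,
                            cv_folds = 5L, seed = 1L, tie_tol = 0.05) {
  if (length(schemes) < 2) stop("need >= 2 schemes", call. = FALSE)
  if (is.vector(unit_responses))
    unit_responses <- matrix(unit_responses, ncol = 1)
  designs <- lapply(schemes, function(s) build_design_matrix(words, s))
  names(designs) <- schemes
  nu <- ncol(unit_responses)
  cvr <- matrix(NA_real_, nu, length(schemes),
                dimnames = list(NULL, schemes))
  for (u in seq_len(nu)) {
    for (s in schemes)
      cvr[u, s] <- fit_encoding(unit_responses[, u], designs[[s]],
                                cv_folds = cv_folds,
                                seed = .child_seed(seed, u))$cv_r
  }
  best <- apply(cvr, 1, which.max)
  second <- apply(cvr, 1, function(r) max(r[-which.max(r)]))
  out <- data.frame(unit = seq_len(nu))
  for (s in schemes) out[[paste0("cv_r_", s)]] <- cvr[, s]
  out$winner <- schemes[best]
  out$tie <- (cvr[cbind(seq_len(nu), best)] - second) < tie_tol
  out
}

#' Position tuning curves from encoding fits
#'
#' For each fit, coefficients are reshaped to letters x slots and averaged
#' across letters, giving a length-`frame_slots` position profile. Units are
#' grouped by the slot of their profile peak; each profile is normalized by
#' its own maximum and averaged within group.
#'
#' @param fits list of `encoding_fit` objects sharing a scheme.
#' @param alphabet alphabet used in the design matrix.
#' @param frame_slots slot count.
#' @return List of groups, each with `group` (preferred slot), `n_units`,
#'   and `curve` (length-`frame_slots` mean normalized profile, max <= 1).
#'   Units with an all-zero coefficient vector are dropped with a warning.
#' @export
position_tuning <- function(fits, alphabet = letters, frame_slots = 8L) {
  na <- length(alphabet)
  profs <- list(); groups <- integer(0)
  dropped <- 0L
  for (f in fits) {
    b <- matrix(f$b, na, frame_slots)
    prof <- colMeans(b)
    if (all(prof == 0)) { dropped <- dropped + 1L; next }
    prof <- prof / max(prof)
    profs[[length(profs) + 1L]] <- prof
    groups <- c(groups, which.max(prof))
  }
  if (dropped) warning(dropped, " unit(s) dropped: all-zero coefficients")
  lapply(sort(unique(groups)), function(gr) {
    sel <- which(groups == gr)
    list(group = gr, n_units = length(sel),
         curve = colMeans(do.call(rbind, profs[sel])))
  })
}
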