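# Scaled-down literacy experiment: train an illiterate (objects-only) and a
# literate (objects + words) network pair from a common base at desk scale,
# then run the dissection suite on both. This is a qualitative mirror of the
# full-scale experiments (which require ImageNet-scale data and GPU
# training), not a reproduction of their printed percentages.

#' Desk-scale experiment profile
#'
#' Bundles every size/parameter choice of the scaled experiment: a 64-pixel
#' canvas (proportionally scaled stimulus ranges), a narrow network, 20
#' frequent French words, procedural object categories, and short two-phase
#' training. The profile-level exclusion threshold for response-profile
#' analysis is expressed in this network's activation units.
#'
#' @param canvas canvas edge (default 64).
#' @param widths block channel widths.
#' @param words training word list.
#' @param n_train_word,n_test_word word variants per word and split.
#' @param n_train_obj,n_test_obj object images per category and split.
#' @param epochs_phase1,epochs_phase2 training epochs per phase.
#' @param batch_size minibatch size.
#' @param loc_words,loc_per_category localizer set sizes.
#' @param k_sd localizer threshold multiplier.
#' @param n_bigrams bigram set size for the dissimilarity analysis.
#' @param probe_size_pt letter size for probe/grid stimuli.
#' @param exclusion profile exclusion threshold (this network's activation
#'   scale).
#' @param max_units_per_layer cap on profiled units per layer.
#' @return A named list profile.
#' @export
scaled_profile <- function(canvas = 64L, widths = c(8L, 16L, 32L, 64L),
                           words = c("les", "est", "par", "mais", "dans",
                                     "pour", "avec", "tout", "bien", "deux",
                                     "comme", "alors", "temps", "grand",
                                     "monde", "chose", "petit", "encore",
                                     "premier", "toujours"),
                           n_train_word = 100L, n_test_word = 20L,
                           n_train_obj = 150L, n_test_obj = 20L,
                           epochs_phase1 = 6L, epochs_phase2 = 8L,
                           batch_size = 32L, loc_words = 200L,
                           loc_per_category = 50L, k_sd = 3,
                           n_bigrams = 49L, probe_size_pt = 50,
                           exclusion = 0.5, max_units_per_layer = 60L) {
  list(canvas = canvas, widths = widths, words = words,
       n_train_word = n_train_word, n_test_word = n_test_word,
       n_train_obj = n_train_obj, n_test_obj = n_test_obj,
       epochs_phase1 = epochs_phase1, epochs_phase2 = epochs_phase2,
       batch_size = batch_size, loc_words = loc_words,
       loc_per_category = loc_per_category, k_sd = k_sd,
       n_bigrams = n_bigrams, probe_size_pt = probe_size_pt,
       exclusion = exclusion, max_units_per_layer = max_units_per_layer)
}

#' Run the scaled literacy experiment
#'
#' Trains the illiterate/literate network pair from one base network, then
#' (1) counts word-selective units per layer in both networks with the
#' category localizer, (2) compares mean pairwise bigram dissimilarity per
#' layer between the networks, and (3) categorizes the literate network's
#' word-selective units with the factorial probe design.
#'
#' @param seed experiment seed (controls data generation, initialization,
#'   minibatch order).
#' @param profile a [scaled_profile()].
#' @param verbose print progress.
#' @return List with `accuracy`, `selective` (per-layer counts per network),
#'   `rdm` (per-layer literate-vs-illiterate comparison), `categories`
#'   (per-unit profile categories, literate network), `summary` (layer
#'   proportions), and the two trained `models`.
#' @export
run_literacy_experiment <- function(seed = 1L, profile = scaled_profile(),
                                    verbose = FALSE) {
  p <- profile
  say <- function(...) if (verbose) message(sprintf(...))
  n_obj_classes <- length(object_categories())

  # ---- stimuli ----
  say("generating stimuli (canvas %d)", p$canvas)
  man <- make_training_set(p$words, p$n_train_word, p$n_test_word,
                           seed = .child_seed(seed, "words"),
                           canvas = p$canvas)
  wtr <- man[man$split == "train", ]; wte <- man[man$split == "test", ]
  x_wtr <- render_dataset(wtr, p$canvas); y_wtr <- wtr$label + n_obj_classes
  x_wte <- render_dataset(wte, p$canvas); y_wte <- wte$label + n_obj_classes
  obj_tr <- list(); obj_te <- list(); y_otr <- c(); y_ote <- c()
  for (ci in seq_along(object_categories())) {
    cat_ <- object_categories()[ci]
    imgs <- make_object_images(cat_, p$n_train_obj + p$n_test_obj, p$canvas,
                               seed = .child_seed(seed, paste0("obj", cat_)))
    obj_tr <- c(obj_tr, imgs[seq_len(p$n_train_obj)])
    obj_te <- c(obj_te, imgs[p$n_train_obj + seq_len(p$n_test_obj)])
    y_otr <- c(y_otr, rep(ci, p$n_train_obj))
    y_ote <- c(y_ote, rep(ci, p$n_test_obj))
  }
  x_otr <- as_image_batch(obj_tr); x_ote <- as_image_batch(obj_te)

  # ---- phase 1: objects only (illiterate base) ----
  spec <- network_spec(p$canvas, p$widths)
  base <- build_network(spec, n_obj_classes, seed = .child_seed(seed, "init"))
  sch1 <- training_schedule(p$epochs_phase1, batch_size = p$batch_size)
  say("phase 1: %d object images, %d epochs", dim(x_otr)[4], p$epochs_phase1)
  base <- train_cornet(base, x_otr, y_otr, sch1,
                       seed = .child_seed(seed, "ph1"),
                       tests = list(objects = list(x = x_ote, y = y_ote)),
                       verbose = verbose)

  # ---- phase 2 ----
  sch2 <- training_schedule(p$epochs_phase2, batch_size = p$batch_size)
  say("phase 2 (literate): +%d word categories", length(p$words))
  lit <- extend_output(base, length(p$words),
                       seed = .child_seed(seed, "ext"))
  x_all <- array(c(x_otr, x_wtr), dim = c(dim(x_otr)[1:3],
                                          dim(x_otr)[4] + dim(x_wtr)[4]))
  y_all <- c(y_otr, y_wtr)
  lit <- train_cornet(lit, x_all, y_all, sch2,
                      seed = .child_seed(seed, "ph2"),
                      tests = list(objects = list(x = x_ote, y = y_ote),
                                   words = list(x = x_wte, y = y_wte)),
                      verbose = verbose)
  say("phase 2 (illiterate control): objects only, equivalent duration")
  ill <- train_cornet(base, x_otr, y_otr, sch2,
                      seed = .child_seed(seed, "ph2i"),
                      tests = list(objects = list(x = x_ote, y = y_ote)),
                      verbose = verbose)
  metrics_lit <- attr(lit, "metrics"); metrics_ill <- attr(ill, "metrics")
  accuracy <- list(
    literate_words = utils::tail(metrics_lit$acc_words, 1),
    literate_objects = utils::tail(metrics_lit$acc_objects, 1),
    illiterate_objects = utils::tail(metrics_ill$acc_objects, 1))

  # ---- localizer: word-selective units per layer ----
  say("localizer")
  loc <- make_localizer_set(p$words, p$loc_words, p$loc_per_category,
                            seed = .child_seed(seed, "loc"),
                            canvas = p$canvas)
  layers <- c("V1", "V2", "V4", "IT", "avgIT")
  selective <- list()
  loc_stores <- list()
  for (mdl in c("literate", "illiterate")) {
    st <- record_activations(if (mdl == "literate") lit else ill,
                             loc$images, layers)
    loc_stores[[mdl]] <- st
    res <- lapply(layers, function(ly) {
      m <- st$layers[[ly]]
      find_word_selective(m[loc$labels == "word", , drop = FALSE],
                          lapply(split(seq_along(loc$labels)[
                            loc$labels != "word"],
                            loc$labels[loc$labels != "word"]),
                            function(i) m[i, , drop = FALSE]),
                          k_sd = p$k_sd)
    })
    names(res) <- layers
    selective[[mdl]] <- res
  }
  sel_counts <- lapply(selective, count_selective_by_layer)

  # ---- representational dissimilarity over bigrams ----
  say("bigram dissimilarity")
  bg <- make_bigram_set(n_bigrams = p$n_bigrams,
                        seed = .child_seed(seed, "bg"),
                        size_pt = p$probe_size_pt, canvas = p$canvas)
  rdm_res <- lapply(list(literate = lit, illiterate = ill), function(m) {
    st <- record_activations(m, bg$stimuli, layers)
    res <- lapply(layers, function(ly) mean_pairwise(st, ly))
    names(res) <- layers
    res
  })
  rdm_cmp <- compare_networks(rdm_res$literate, rdm_res$illiterate)

  # ---- response profiles of the literate network's selective units ----
  say("response profiles")
  grid <- make_single_letter_grid(LETTERS, size_pt = p$probe_size_pt,
                                  canvas = p$canvas)
  grid_store <- record_activations(lit, grid$stimuli, layers)
  probe_cache <- list()
  cat_rows <- list()
  for (ly in c("V4", "IT", "avgIT")) {
    sel <- selective$literate[[ly]]
    units <- sel$unit[sel$selective]
    if (length(units) > p$max_units_per_layer)
      units <- units[seq_len(p$max_units_per_layer)]
    for (u in units) {
      lt <- letter_tuning(grid_store$layers[[ly]][, u], grid$meta)
      key <- paste0(lt$best_letter, lt$worst_letter)
      if (lt$best_letter == lt$worst_letter) next  # flat tuning
      if (is.null(probe_cache[[key]])) {
        des <- make_factorial_probe(lt$best_letter, lt$worst_letter,
                                    size_pt = p$probe_size_pt,
                                    canvas = p$canvas)
        probe_cache[[key]] <- list(
          design = des,
          store = record_activations(lit, des$stimuli, c("V4", "IT", "avgIT")))
      }
      pc <- probe_cache[[key]]
      cl <- classify_profile(pc$store$layers[[ly]][, u], pc$design,
                             exclusion = p$exclusion)
      cat_rows[[length(cat_rows) + 1L]] <-
        data.frame(layer = ly, unit = u, best = lt$best_letter,
                   worst = lt$worst_letter, category = cl$category)
    }
  }
  categories <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(layer = character(), unit = integer(), best = character(),
               worst = character(), category = character())
  summary_ <- if (nrow(categories)) layer_summary(categories) else NULL

  list(seed = seed, profile = p, accuracy = accuracy,
       metrics = list(literate = metrics_lit, illiterate = metrics_ill),
       selective_counts = sel_counts, selective = selective,
       rdm = rdm_cmp, rdm_means = rdm_res, categories = categories,
       summary = summary_, models = list(literate = lit, illiterate = ill))
}
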