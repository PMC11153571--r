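# Shared end-to-end phantom study used by the acceptance tests.
#
# Conditions (fixed): 4 training chambers x 5 timepoints at 512 x 384
# (20 images), default phantom parameters; patch-64 and patch-256 models
# with identical corpora, split seed, epoch budget (6) and learning rate;
# 2 held-out chambers, final 3 timepoints each (6 unseen images) for
# full-image evaluation. Everything derives from STUDY_SEED. The study is
# computed once per test session and memoized.

STUDY_SEED <- 42L

.study_env <- new.env(parent = emptyenv())

study_chambers <- function(seed = STUDY_SEED, n = 4L) {
  lapply(seq_len(n), function(i)
    render_phantom(phantom_config(seed = seed + i),
                   chamber_id = sprintf("C%02d", i),
                   treatment = c("Full", "N", "K", "Ca")[(i - 1L) %% 4L + 1L]))
}

study_corpus <- function(chambers, patch_size) {
  sets <- list()
  for (ch in chambers) {
    for (i in seq_along(ch$scans)) {
      sets[[length(sets) + 1L]] <-
        extract_patches(ch$scans[[i]], ch$masks[[i]], patch_size)
    }
  }
  ps <- combine_patch_sets(sets)
  ps <- filter_sparse_patches(ps)
  split_dataset(ps, seed = STUDY_SEED + 7L)
}

study_train <- function(patchset, patch_size) {
  batch <- if (patch_size >= 256L) 2L else 8L
  model <- build_resunet(model_config(levels = 3L, base_channels = 8L,
                                      seed = STUDY_SEED + 5L))
  train_resunet(model, patchset, epochs = 6L, batch_size = batch,
                lr = 1e-3, seed = STUDY_SEED + 9L)
}

get_study <- function() {
  if (!is.null(.study_env$study)) return(.study_env$study)
  chambers <- study_chambers()
  unseen <- lapply(1:2, function(i)
    render_phantom(phantom_config(seed = STUDY_SEED + 100L + i),
                   chamber_id = sprintf("U%02d", i)))
  models <- list()
  for (s in c(64L, 256L)) {
    ps <- study_corpus(chambers, s)
    models[[as.character(s)]] <- study_train(ps, s)
  }
  # full-image root IOU on the 6 unseen images (final 3 timepoints each)
  iou <- list()
  for (s in c(64L, 256L)) {
    vals <- c()
    for (ch in unseen) {
      for (tp in 3:5) {
        pred <- predict_full_image(models[[as.character(s)]],
                                   ch$scans[[tp]], tile = s, overlap = 0.25)
        vals <- c(vals, segmentation_metrics(ch$masks[[tp]],
                                             pred$class_map)$iou)
      }
    }
    iou[[as.character(s)]] <- vals
  }
  # patch-64 predictions on all 20 training-corpus chamber-timepoints,
  # post-processed per chamber with the default morphology parameters
  pred_counts <- c()
  true_counts <- c()
  params <- morpho_params()
  for (ch in chambers) {
    maps <- lapply(seq_along(ch$scans), function(i)
      predict_full_image(models[["64"]], ch$scans[[i]],
                         tile = 64L, overlap = 0.25)$class_map)
    hull <- stack_hull(prediction_stack(maps, ch$chamber_id), params)
    for (i in seq_along(maps)) {
      cleaned <- clean_prediction(maps[[i]], hull, params)
      pred_counts <- c(pred_counts, root_pixel_count(cleaned))
      true_counts <- c(true_counts, ch$true_root_pixel_counts[i])
    }
  }
  .study_env$study <- list(chambers = chambers, unseen = unseen,
                           models = models, iou = iou,
                           pred_counts = pred_counts,
                           true_counts = true_counts)
  .study_env$study
}
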