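#' Run configuration
#'
#' Builds and validates the configuration for a full pipeline run. The
#' blocks mirror the stage parameters; unspecified fields take the
#' defaults below. Configurations can come from a YAML file (one file per
#' run) via `run_config(yaml = "cfg.yaml")`; explicit arguments override
#' YAML values. The global `seed` feeds every stage through fixed,
#' documented offsets so a run is reproducible end to end.
#'
#' @param out Output directory for the run.
#' @param seed Global integer seed.
#' @param yaml Optional YAML file with blocks
#'   `simulate/data/model/train/postprocess/biomass`.
#' @param ... Named blocks overriding YAML/defaults (each a list), e.g.
#'   `data = list(patch_size = 64)`.
#' @return A validated `run_config`.
#' @export
run_config <- function(out = "rootseg_run", seed = 1L, yaml = NULL, ...) {
  defaults <- list(
    simulate = list(enabled = TRUE, n_chambers = 4L, n_timepoints = 5L,
                    image_size = c(512L, 384L), branch_prob = 0.3,
                    root_thickness_px = 5L, growth_steps_per_timepoint = 80L,
                    artifact_density = 40,
                    background_fraction_target = 0.8,
                    treatments = c("Full", "N", "K", "Ca")),
    data = list(patch_size = 64L, min_annotated_fraction = 0.20,
                fractions = c(0.8, 0.1, 0.1), by_chamber = FALSE,
                manifest = NULL),
    model = list(levels = 3L, base_channels = 8L, dropout = 0.2),
    train = list(epochs = 6L, batch_size = 8L, lr = 1e-3, augment = TRUE),
    predict = list(tile = 64L, overlap = 0.25),
    postprocess = list(dilation_radius = 2L, erosion_radius = 0L,
                       area_opening_min = 64L, area_closing_min = 64L,
                       optimize = FALSE, erosion_grid = 0:3),
    biomass = list(weights_csv = NULL)
  )
  cfg <- defaults
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml)
    ycfg <- yaml::read_yaml(yaml)
    for (blk in intersect(names(ycfg), names(cfg))) {
      cfg[[blk]][names(ycfg[[blk]])] <- ycfg[[blk]]
    }
    if (!is.null(ycfg$seed)) seed <- ycfg$seed
    if (!is.null(ycfg$out)) out <- ycfg$out
  }
  dots <- list(...)
  for (blk in names(dots)) {
    if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
    cfg[[blk]][names(dots[[blk]])] <- dots[[blk]]
  }
  cfg$out <- out
  cfg$seed <- as.integer(seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L,
            cfg$data$patch_size >= 8L,
            cfg$data$min_annotated_fraction >= 0,
            cfg$data$min_annotated_fraction <= 1,
            abs(sum(cfg$data$fractions) - 1) < 1e-8,
            cfg$model$levels >= 2L, cfg$train$epochs >= 1L,
            cfg$predict$tile %% 2L^(cfg$model$levels - 1L) == 0L)
  if (!cfg$simulate$enabled && is.null(cfg$data$manifest)) {
    stop("config error: simulate disabled and no data manifest given")
  }
  invisible(cfg)
}

stage_log <- function(report, stage, t0, status, detail = "") {
  elapsed <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  message(sprintf("[%s] %s (%.2fs) %s", stage, status, elapsed, detail))
  report$stages <- rbind(report$stages,
                         data.frame(stage = stage, status = status,
                                    seconds = elapsed,
                                    stringsAsFactors = FALSE))
  report
}

#' Run the full pipeline
#'
#' Executes simulate (optional), patch extraction, training, full-image
#' prediction, convex-hull/morphology post-processing, and biomass
#' quantification, writing each stage's outputs under `config$out`.
#' Stages whose outputs already exist are skipped, so an interrupted run
#' resumes from its last completed stage.
#'
#' @param config A [run_config()].
#' @return A run report: list with `stages` (status/timing data frame) and
#'   the key output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out, "run_config.yaml"))
  report <- list(stages = data.frame())
  seed <- config$seed

  # -- simulate ---------------------------------------------------------
  t0 <- Sys.time()
  data_dir <- file.path(out, "data")
  manifest_path <- if (config$simulate$enabled) {
    file.path(data_dir, "manifest.csv")
  } else config$data$manifest
  if (config$simulate$enabled) {
    if (file.exists(manifest_path)) {
      report <- stage_log(report, "simulate", t0, "skipped", "(resume)")
    } else {
      sim <- config$simulate
      for (i in seq_len(sim$n_chambers)) {
        pc <- phantom_config(seed = seed + 1000L + i,
                             image_size = sim$image_size,
                             n_timepoints = sim$n_timepoints,
                             branch_prob = sim$branch_prob,
                             root_thickness_px = sim$root_thickness_px,
                             growth_steps_per_timepoint =
                               sim$growth_steps_per_timepoint,
                             artifact_density = sim$artifact_density,
                             background_fraction_target =
                               sim$background_fraction_target)
        series <- render_phantom(pc, chamber_id = sprintf("C%02d", i),
                                 treatment = sim$treatments[
                                   (i - 1L) %% length(sim$treatments) + 1L])
        write_phantom_dataset(series, data_dir, append = i > 1L)
      }
      report <- stage_log(report, "simulate", t0, "done",
                          paste0(config$simulate$n_chambers, " chambers"))
    }
  } else {
    report <- stage_log(report, "simulate", t0, "skipped", "(disabled)")
  }
  manifest <- read_manifest(manifest_path)

  # -- patches ----------------------------------------------------------
  t0 <- Sys.time()
  patches_path <- file.path(out, "patches.rds")
  if (file.exists(patches_path)) {
    report <- stage_log(report, "patches", t0, "skipped", "(resume)")
  } else {
    if (!"mask_path" %in% names(manifest)) {
      stop("data error: manifest has no mask_path column: ", manifest_path)
    }
    sets <- lapply(seq_len(nrow(manifest)), function(i) {
      scan <- root_scan(read_scan_png(manifest$scan_path[i]),
                        chamber_id = manifest$chamber_id[i],
                        timepoint = manifest$timepoint[i],
                        treatment = manifest$treatment[i])
      extract_patches(scan, read_mask_png(manifest$mask_path[i]),
                      config$data$patch_size)
    })
    ps <- combine_patch_sets(sets)
    ps <- filter_sparse_patches(ps, config$data$min_annotated_fraction)
    ps <- split_dataset(ps, config$data$fractions, seed = seed + 2L,
                        by_chamber = config$data$by_chamber)
    saveRDS(ps, patches_path)
    report <- stage_log(report, "patches", t0, "done",
                        paste0(length(ps$patches), " patches"))
  }

  # -- train ------------------------------------------------------------
  t0 <- Sys.time()
  model_path <- file.path(out, "model.rds")
  if (file.exists(model_path)) {
    report <- stage_log(report, "train", t0, "skipped", "(resume)")
  } else {
    ps <- readRDS(patches_path)
    model <- build_resunet(model_config(levels = config$model$levels,
                                        base_channels = config$model$base_channels,
                                        dropout = config$model$dropout,
                                        seed = seed + 3L))
    aug <- if (isTRUE(config$train$augment)) augmentation_config() else NULL
    model <- train_resunet(model, ps, epochs = config$train$epochs,
                           batch_size = config$train$batch_size,
                           lr = config$train$lr, seed = seed + 4L,
                           augment = aug)
    save_model(model, model_path)
    utils::write.csv(model$history, file.path(out, "history.csv"),
                     row.names = FALSE)
    report <- stage_log(report, "train", t0, "done",
                        sprintf("final val loss %.4f",
                                utils::tail(model$history$val_loss, 1L)))
  }

  # -- predict ----------------------------------------------------------
  t0 <- Sys.time()
  pred_dir <- file.path(out, "predictions")
  metrics_path <- file.path(out, "metrics.csv")
  if (file.exists(metrics_path)) {
    report <- stage_log(report, "predict", t0, "skipped", "(resume)")
  } else {
    model <- load_model(model_path)
    dir.create(pred_dir, showWarnings = FALSE)
    mrows <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      pred <- predict_full_image(model, read_scan_png(manifest$scan_path[i]),
                                 tile = config$predict$tile,
                                 overlap = config$predict$overlap)
      ppath <- file.path(pred_dir, sprintf("%s_t%02d_pred.png",
                                           manifest$chamber_id[i],
                                           manifest$timepoint[i]))
      write_mask_png(pred$class_map, ppath)
      row <- data.frame(image_id = sprintf("%s_t%02d", manifest$chamber_id[i],
                                           manifest$timepoint[i]),
                        accuracy = NA_real_, precision = NA_real_,
                        recall = NA_real_, iou = NA_real_, auc = NA_real_)
      if ("mask_path" %in% names(manifest) &&
          file.exists(manifest$mask_path[i])) {
        truth <- read_mask_png(manifest$mask_path[i])
        sm <- segmentation_metrics(truth, pred$class_map, pred$probs)
        row[, c("accuracy", "precision", "recall", "iou", "auc")] <-
          unlist(sm[c("accuracy", "precision", "recall", "iou", "auc")])
      }
      mrows[[i]] <- row
    }
    utils::write.csv(do.call(rbind, mrows), metrics_path, row.names = FALSE)
    report <- stage_log(report, "predict", t0, "done",
                        paste0(nrow(manifest), " images"))
  }

  # -- postprocess ------------------------------------------------------
  t0 <- Sys.time()
  clean_dir <- file.path(out, "cleaned")
  pp_report_path <- file.path(out, "postprocess.json")
  if (file.exists(pp_report_path)) {
    report <- stage_log(report, "postprocess", t0, "skipped", "(resume)")
  } else {
    dir.create(clean_dir, showWarnings = FALSE)
    params <- morpho_params(dilation_radius = config$postprocess$dilation_radius,
                            erosion_radius = config$postprocess$erosion_radius,
                            area_opening_min = config$postprocess$area_opening_min,
                            area_closing_min = config$postprocess$area_closing_min)
    pp <- list()
    for (ch in unique(manifest$chamber_id)) {
      rows <- manifest[manifest$chamber_id == ch, ]
      rows <- rows[order(rows$timepoint), ]
      maps <- lapply(seq_len(nrow(rows)), function(i)
        read_mask_png(file.path(pred_dir, sprintf("%s_t%02d_pred.png",
                                                  ch, rows$timepoint[i]))))
      stack <- prediction_stack(maps, chamber_id = ch,
                                timepoints = rows$timepoint)
      hull <- stack_hull(stack, params)
      for (i in seq_len(nrow(rows))) {
        cleaned <- clean_prediction(maps[[i]], hull, params)
        write_mask_png(matrix(as.integer(cleaned) * 2L, nrow(cleaned)),
                       file.path(clean_dir, sprintf("%s_t%02d_clean.png",
                                                    ch, rows$timepoint[i])))
      }
      pp[[ch]] <- list(hull_vertices = hull$vertices,
                       params = unclass(params))
    }
    jsonlite::write_json(pp, pp_report_path, auto_unbox = TRUE, digits = NA)
    report <- stage_log(report, "postprocess", t0, "done",
                        paste0(length(pp), " chambers"))
  }

  # -- biomass ----------------------------------------------------------
  t0 <- Sys.time()
  biomass_path <- file.path(out, "biomass.csv")
  if (file.exists(biomass_path)) {
    report <- stage_log(report, "biomass", t0, "skipped", "(resume)")
  } else {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      cleaned <- read_mask_png(file.path(clean_dir,
                                         sprintf("%s_t%02d_clean.png",
                                                 manifest$chamber_id[i],
                                                 manifest$timepoint[i])))
      data.frame(chamber_id = manifest$chamber_id[i],
                 treatment = if ("treatment" %in% names(manifest))
                   manifest$treatment[i] else NA_character_,
                 timepoint = manifest$timepoint[i],
                 root_pixels = root_pixel_count(cleaned == 2L),
                 stringsAsFactors = FALSE)
    })
    bio <- do.call(rbind, rows)
    utils::write.csv(bio, biomass_path, row.names = FALSE)
    if (!is.null(config$biomass$weights_csv)) {
      w <- utils::read.csv(config$biomass$weights_csv, stringsAsFactors = FALSE)
      last <- stats::aggregate(timepoint ~ chamber_id, bio, max)
      fin <- merge(merge(bio, last), w, by = "chamber_id")
      reg <- compare_to_scale(l2_normalize(fin$root_pixels),
                              l2_normalize(fin$weight_mg))
      jsonlite::write_json(unclass(reg), file.path(out, "regression.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    report <- stage_log(report, "biomass", t0, "done",
                        paste0(nrow(bio), " chamber-timepoints"))
  }

  report$out <- out
  report$manifest <- manifest_path
  report$model <- model_path
  report$biomass <- biomass_path
  invisible(report)
}
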