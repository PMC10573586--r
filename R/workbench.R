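# End-to-end experiment orchestration: phantom cohort -> pretraining ->
# k-fold fine-tuning -> evaluation -> XAI, with a validated config, derived
# seeds and fully reproducible outputs.

#' Default experiment configuration
#'
#' CI-scale defaults: a cohort sized for the reduced 8-fold composition
#' ([ci_composition()]), the compact default encoder, shared (not
#' per-fold) autoencoder pretraining, and occlusion-based XAI on a few
#' held-out patches. Every field can be overridden; unknown keys are
#' rejected by [run_experiment()].
#'
#' @return Nested configuration list.
#' @export
default_experiment_config <- function() {
  comp <- ci_composition()
  size <- composition_cohort_size(comp)
  list(
    cohort = list(
      n_control = size[1], n_albinism = size[2],
      dataset_tags = c("siteA", "siteB", "siteC"),
      effect = list(width_ratio = 0.7, tract_angle_offset_deg = 15,
                    central_boost = 0.15, variation_cv = 0.05,
                    noise_sigma = 0.05, noise_model = "rician",
                    vessel_probability = 0.3)
    ),
    model = list(
      encoder = list(n_blocks = 3, channels_per_block = c(8, 16, 32),
                     kernel = 3, downsample_factor = 2, latent_dim = 64),
      head = list(hidden = 16)
    ),
    pretrain = list(epochs = 8, batch_size = 32, lr = 1e-3,
                    holdout_fraction = 0.2, per_fold = FALSE),
    train = list(k = 8,
                 composition = lapply(unclass(comp), as.integer),
                 epochs = 12, batch_size = 32, lr = 1e-3,
                 criterion = "max_dev_auroc", freeze_encoder = TRUE,
                 augment_mm = c(1.5, 1.5, 0.75)),
    xai = list(window_voxels = c(4, 4, 2), stride_voxels = c(2, 2, 1),
               fill = "background_mean", top_fraction = 0.05,
               n_patches = 4),
    seed = 1L
  )
}

# Reject config keys that the template does not know (typo protection);
# recurses through named lists.
.validate_config_names <- function(config, template, path = "config") {
  if (!is.list(config) || !is.list(template)) return(invisible(TRUE))
  if (is.null(names(template)) || any(names(template) == "")) {
    return(invisible(TRUE))
  }
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("run_experiment: unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(config)) {
    .validate_config_names(config[[k]], template[[k]],
                           paste(path, k, sep = "$"))
  }
  invisible(TRUE)
}

# Deep-merge user overrides into the defaults.
.merge_config <- function(defaults, overrides) {
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], overrides[[k]])
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Load an experiment configuration file
#'
#' YAML or JSON; keys override [default_experiment_config()].
#'
#' @param path Config file path.
#' @return Full configuration list.
#' @export
load_experiment_config <- function(path) {
  overrides <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- .merge_config(default_experiment_config(), overrides)
  .validate_config_names(cfg, default_experiment_config())
  cfg
}

# Evaluate a trained classifier on one test group at a fixed threshold.
.evaluate_group <- function(scores, labels, threshold) {
  counts <- confusion_at_threshold(scores, labels, threshold)
  metrics <- compute_metrics(counts)
  metrics$auroc <- if (length(unique(labels)) == 2) {
    roc_and_auroc(scores, labels)$auroc
  } else NA_real_
  list(counts = counts, metrics = metrics)
}

#' Run a full experiment
#'
#' Executes phantom generation, autoencoder pretraining on chiasm-excluded
#' patches, k-fold classifier fine-tuning with minority upsampling and
#' augmentation, per-fold optimal-threshold evaluation on TEST1/TEST2,
#' fold aggregation, and occlusion-based XAI with localization scoring.
#' Two runs with an identical config and seed produce identical
#' `summary.json`. Per-fold artifacts (checkpoint, history, split lists,
#' ROC) are written under `out_dir/fold_<i>/`.
#'
#' @param config Configuration (see [default_experiment_config()]);
#'   partial configs are merged into the defaults.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides `config$seed` when given).
#' @return The results bundle (also serialized to `out_dir/summary.json`),
#'   a list with `config`, per-fold results, aggregate tables and XAI
#'   scores.
#' @export
run_experiment <- function(config = list(), out_dir = tempfile("chiasm_run"),
                           seed = NULL) {
  cfg <- .merge_config(default_experiment_config(), config)
  .validate_config_names(cfg, default_experiment_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "INCOMPLETE"))
  stage <- "cohort"
  result <- tryCatch({
    effect <- do.call(phantom_effect_config, cfg$cohort$effect)
    manifest <- generate_cohort(cfg$cohort$n_control, cfg$cohort$n_albinism,
                                effect_config = effect,
                                out_dir = file.path(out_dir, "cohort"),
                                seed = .derive_seed(cfg$seed, 101),
                                dataset_tags = cfg$cohort$dataset_tags)
    cohort <- load_cohort_patches(manifest, normalize = TRUE, masks = TRUE)

    stage <- "splits"
    comp <- do.call(fold_composition, cfg$train$composition)
    splits <- make_fold_splits(manifest, k = cfg$train$k, composition = comp,
                               seed = .derive_seed(cfg$seed, 202))

    stage <- "pretrain"
    enc_cfg <- do.call(encoder_config, cfg$model$encoder)
    excluded <- chiasm_excluded_patches(cohort)
    shared_encoder <- NULL
    if (!isTRUE(cfg$pretrain$per_fold)) {
      ae <- build_autoencoder(enc_cfg, seed = .derive_seed(cfg$seed, 303))
      pre <- pretrain_autoencoder(ae, excluded,
                                  epochs = cfg$pretrain$epochs,
                                  batch_size = cfg$pretrain$batch_size,
                                  lr = cfg$pretrain$lr,
                                  holdout_fraction = cfg$pretrain$holdout_fraction,
                                  seed = .derive_seed(cfg$seed, 304))
      shared_encoder <- pre$encoder
      utils::write.csv(pre$history,
                       file.path(out_dir, "pretrain_history.csv"),
                       row.names = FALSE)
    }

    folds <- vector("list", length(splits))
    for (fi in seq_along(splits)) {
      stage <- sprintf("fold %d", fi - 1)
      sp <- splits[[fi]]
      fold_seed <- .derive_seed(cfg$seed, 400, fi)
      fold_dir <- file.path(out_dir, sprintf("fold_%d", fi - 1))
      dir.create(fold_dir, showWarnings = FALSE)

      encoder <- shared_encoder
      if (isTRUE(cfg$pretrain$per_fold)) {
        ae <- build_autoencoder(enc_cfg, seed = fold_seed)
        pre <- pretrain_autoencoder(
          ae, excluded[c(sp$train_ids, sp$dev_ids)],
          epochs = cfg$pretrain$epochs,
          batch_size = cfg$pretrain$batch_size, lr = cfg$pretrain$lr,
          holdout_fraction = cfg$pretrain$holdout_fraction,
          seed = fold_seed)
        encoder <- pre$encoder
      }
      clf <- build_classifier(encoder, head_config = cfg$model$head,
                              seed = fold_seed)
      sub <- function(ids) manifest[match(ids, manifest$sample_id), ]
      train_tab <- upsample_minority(sub(sp$train_ids), seed = fold_seed)
      dev_tab <- upsample_minority(sub(sp$dev_ids), seed = fold_seed)
      fit <- finetune_classifier(
        clf,
        train = list(table = train_tab, patches = cohort$patches),
        dev = list(table = dev_tab, patches = cohort$patches),
        epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
        lr = cfg$train$lr, seed = fold_seed,
        criterion = cfg$train$criterion,
        freeze_encoder = cfg$train$freeze_encoder,
        augment_mm = cfg$train$augment_mm)

      # per-fold optimal threshold from DEV_TRAIN scores (the originals,
      # unaugmented); using test data here would leak
      dev_scores <- predict_score(fit$model, cohort$patches[sp$dev_ids])
      dev_labels <- cohort$labels[sp$dev_ids]
      dev_roc <- roc_and_auroc(dev_scores, dev_labels)
      threshold <- optimal_threshold(dev_roc$roc)

      eval_group <- function(ids) {
        scores <- predict_score(fit$model, cohort$patches[ids])
        .evaluate_group(scores, cohort$labels[ids], threshold)
      }
      test1 <- eval_group(sp$test1_ids)
      test2 <- eval_group(sp$test2_ids)

      save_checkpoint(fit$model, file.path(fold_dir, "checkpoint.rds"))
      utils::write.csv(fit$history$records,
                       file.path(fold_dir, "history.csv"), row.names = FALSE)
      utils::write.csv(dev_roc$roc, file.path(fold_dir, "roc_dev.csv"),
                       row.names = FALSE)
      for (g in c("train", "dev", "test1", "test2")) {
        writeLines(sp[[paste0(g, "_ids")]],
                   file.path(fold_dir, paste0(g, "_ids.txt")))
      }
      folds[[fi]] <- list(fold_index = sp$fold_index,
                          threshold = threshold,
                          selected_epoch = fit$history$selected_epoch,
                          dev_auroc = dev_roc$auroc,
                          test1 = test1, test2 = test2,
                          model = fit$model)
    }

    stage <- "aggregate"
    agg <- list(
      test1 = aggregate_folds(lapply(folds, `[[`, "test1")),
      test2 = aggregate_folds(lapply(folds, `[[`, "test2"))
    )
    metrics_rows <- do.call(rbind, lapply(seq_along(folds), function(fi) {
      do.call(rbind, lapply(c("test1", "test2"), function(g) {
        m <- folds[[fi]][[g]]$metrics
        data.frame(fold = fi - 1, group = toupper(g),
                   metric = names(unclass(m)),
                   value = as.numeric(unclass(m)))
      }))
    }))
    utils::write.csv(metrics_rows, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)

    stage <- "xai"
    xspec <- occlusion_spec(cfg$xai$window_voxels, cfg$xai$stride_voxels,
                            cfg$xai$fill)
    xai_model <- folds[[1]]$model
    xai_ids <- utils::head(splits[[1]]$test1_ids, cfg$xai$n_patches)
    xai_rows <- lapply(xai_ids, function(id) {
      amap <- occlusion_map(xai_model, cohort$patches[[id]], xspec)
      mask <- cohort$masks[[id]]
      write_attribution(.attribution_map(amap$values, amap$method, id),
                        file.path(out_dir, paste0("occlusion_", id,
                                                  ".nii.gz")))
      data.frame(sample_id = id, label = cohort$labels[[id]],
                 localization = localization_score(amap, mask,
                                                   cfg$xai$top_fraction),
                 mask_fraction = mean(mask > 0))
    })
    xai_scores <- do.call(rbind, xai_rows)
    utils::write.csv(xai_scores, file.path(out_dir, "xai_localization.csv"),
                     row.names = FALSE)
    avg <- class_average_and_difference(
      cohort$patches[splits[[1]]$train_ids],
      cohort$labels[splits[[1]]$train_ids])
    geom_aff <- diag(4); geom_aff[1:3, 4] <- -(patch_geometry()$dims - 1) / 2
    for (nm in names(avg)) {
      write_volume(volume(avg[[nm]], geom_aff),
                   file.path(out_dir, paste0("classavg_", nm, ".nii.gz")))
    }

    stage <- "summary"
    summary <- list(
      config = cfg,
      seed = cfg$seed,
      folds = lapply(folds, function(f) {
        list(fold_index = f$fold_index, threshold = f$threshold,
             selected_epoch = f$selected_epoch, dev_auroc = f$dev_auroc,
             test1 = list(counts = unclass(f$test1$counts),
                          metrics = unclass(f$test1$metrics)),
             test2 = list(counts = unclass(f$test2$counts),
                          metrics = unclass(f$test2$metrics)))
      }),
      aggregate = list(
        test1 = list(metrics = agg$test1$metrics,
                     confusion = unclass(agg$test1$confusion)),
        test2 = list(metrics = agg$test2$metrics,
                     confusion = unclass(agg$test2$confusion))
      ),
      xai = xai_scores
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    summary$models <- lapply(folds, `[[`, "model")
    summary
  }, error = function(e) {
    # mark partial outputs so a half-written bundle is never mistaken for
    # a completed run
    writeLines(paste0("failed at stage: ", stage),
               file.path(out_dir, "INCOMPLETE"))
    stop("run_experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Audit a results bundle
#'
#' Recomputes the aggregate tables in `summary.json` from the persisted
#' per-fold `metrics.csv` and checks agreement to 1e-8; returns TRUE or
#' raises an error describing the mismatch.
#'
#' @param out_dir Directory written by [run_experiment()].
#' @return TRUE, invisibly.
#' @export
audit_experiment <- function(out_dir) {
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                                 simplifyVector = TRUE)
  metrics <- utils::read.csv(file.path(out_dir, "metrics.csv"))
  for (g in c("test1", "test2")) {
    tab <- summary$aggregate[[g]]$metrics
    sub <- metrics[metrics$group == toupper(g), ]
    for (i in seq_len(nrow(tab))) {
      vals <- sub$value[sub$metric == tab$metric[i]]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      if (abs(mean(vals) - tab$mean[i]) > 1e-8) {
        stop("audit_experiment: ", g, " ", tab$metric[i],
             " mean mismatch: summary ", tab$mean[i], " vs recomputed ",
             mean(vals), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
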