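# Fold construction, class-imbalance handling, autoencoder pretraining and
# classifier fine-tuning with checkpoint selection.

#' Per-fold group composition
#'
#' The evaluation protocol splits a cohort, per fold, into four disjoint
#' groups: TRAIN (classifier training), DEV_TRAIN (epoch monitoring and
#' checkpoint/threshold selection), TEST1 (small, class-balanced) and TEST2
#' (maximally imbalanced, the realistic-prevalence falsification set). Each
#' argument is `c(n_control, n_albinism)`.
#'
#' `paper_composition()` is the clinical protocol's printed composition
#' (TRAIN 1274/23, DEV_TRAIN 216/4, TEST1 4/4, TEST2 214/1);
#' `ci_composition()` is roughly 8x smaller per group (TRAIN 160/8,
#' DEV_TRAIN 28/4, TEST1 4/4, TEST2 26/1) so a full 8-fold run stays within
#' CPU-minutes.
#'
#' @param train,dev,test1,test2 Two-element integer vectors
#'   `c(control, albinism)`.
#' @return A `fold_composition` list.
#' @export
fold_composition <- function(train, dev, test1, test2) {
  comp <- list(train = as.integer(train), dev = as.integer(dev),
               test1 = as.integer(test1), test2 = as.integer(test2))
  stopifnot(all(vapply(comp, length, 0L) == 2L),
            all(unlist(comp) >= 0L))
  if (comp$test1[1] != comp$test1[2]) {
    stop("fold_composition: TEST1 must be class-balanced", call. = FALSE)
  }
  structure(comp, class = "fold_composition")
}

#' @rdname fold_composition
#' @export
paper_composition <- function() {
  fold_composition(train = c(1274, 23), dev = c(216, 4),
                   test1 = c(4, 4), test2 = c(214, 1))
}

#' @rdname fold_composition
#' @export
ci_composition <- function() {
  fold_composition(train = c(160, 8), dev = c(28, 4),
                   test1 = c(4, 4), test2 = c(26, 1))
}

#' Cohort size implied by a composition
#'
#' @param composition A [fold_composition()].
#' @return `c(n_control, n_albinism)` totals.
#' @export
composition_cohort_size <- function(composition) {
  Reduce(`+`, unclass(composition))
}

#' Build the k-fold split structure
#'
#' Within each class, samples are ordered by a seeded shuffle stratified
#' over dataset tags (tags interleaved round-robin), the ordering is
#' rotated by `floor(fold * n / k)` per fold, and the rotated ordering is
#' cut into TEST1, TEST2, DEV_TRAIN and TRAIN segments of the sizes given
#' by `composition`. The four groups are pairwise disjoint and cover the
#' cohort; the rotation guarantees every sample is held out in a test
#' group in at least one fold whenever the combined test size is at least
#' `n / k` per class.
#'
#' @param manifest Cohort manifest (data.frame from [generate_cohort()] or
#'   [load_manifest()]).
#' @param k Number of folds (default 8).
#' @param composition A [fold_composition()]; its per-class totals must
#'   equal the cohort's class counts.
#' @param seed Shuffle seed.
#' @return A list of `k` fold splits, each a list with `fold_index`
#'   (0-based), `train_ids`, `dev_ids`, `test1_ids`, `test2_ids` and
#'   `upsampling_factor` (`round(majority/minority)` within TRAIN).
#' @export
make_fold_splits <- function(manifest, k = 8, composition, seed = 1L) {
  stopifnot(k >= 1)
  counts <- c(sum(manifest$label == 0), sum(manifest$label == 1))
  need <- composition_cohort_size(composition)
  if (!all(counts == need)) {
    stop("make_fold_splits: composition requires ", need[1], " controls and ",
         need[2], " albinism samples but the cohort has ", counts[1],
         " and ", counts[2], call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  order_class <- function(lab) {
    rows <- manifest[manifest$label == lab, ]
    ids_by_tag <- split(rows$sample_id, rows$dataset_tag)
    ids_by_tag <- lapply(ids_by_tag, function(ids) ids[sample.int(length(ids))])
    # interleave tags round-robin for stratification
    maxlen <- max(vapply(ids_by_tag, length, 0L))
    out <- character(0)
    for (i in seq_len(maxlen)) {
      for (tag in names(ids_by_tag)) {
        if (i <= length(ids_by_tag[[tag]])) {
          out <- c(out, ids_by_tag[[tag]][i])
        }
      }
    }
    out
  }
  ordering <- list(order_class(0L), order_class(1L))

  lapply(seq_len(k) - 1L, function(f) {
    groups <- list(train = list(), dev = list(), test1 = list(),
                   test2 = list())
    for (cls in 1:2) {
      ids <- ordering[[cls]]
      n <- length(ids)
      if (n == 0) {
        for (g in names(groups)) groups[[g]][[cls]] <- character(0)
        next
      }
      off <- floor(f * n / k)
      rot <- ids[((seq_len(n) - 1 + off) %% n) + 1]
      sizes <- c(test1 = composition$test1[cls],
                 test2 = composition$test2[cls],
                 dev = composition$dev[cls],
                 train = composition$train[cls])
      at <- 0
      for (g in names(sizes)) {
        groups[[g]][[cls]] <- if (sizes[g] > 0) {
          rot[(at + 1):(at + sizes[g])]
        } else character(0)
        at <- at + sizes[g]
      }
    }
    train_ids <- unlist(groups$train, use.names = FALSE)
    n_ctrl <- composition$train[1]
    n_alb <- composition$train[2]
    upsf <- if (min(n_ctrl, n_alb) > 0) {
      as.integer(round(max(n_ctrl, n_alb) / min(n_ctrl, n_alb)))
    } else NA_integer_
    list(fold_index = f,
         train_ids = train_ids,
         dev_ids = unlist(groups$dev, use.names = FALSE),
         test1_ids = unlist(groups$test1, use.names = FALSE),
         test2_ids = unlist(groups$test2, use.names = FALSE),
         upsampling_factor = upsf)
  })
}

#' Upsample the minority class
#'
#' Each minority sample is repeated `round(n_majority / n_minority)` times
#' (repetition only — no sample invention; each repetition later receives
#' an independent augmentation jitter during training). The post-hoc class
#' ratio is therefore within [1/2, 2].
#'
#' @param samples Data.frame with columns `sample_id` and `label` (both
#'   classes must be present).
#' @param seed Reserved for API symmetry; the expansion is deterministic.
#' @return Data.frame with columns `sample_id`, `label`, `rep_index`
#'   (0 for originals, 1.. for repetitions).
#' @export
upsample_minority <- function(samples, seed = 1L) {
  stopifnot(all(c("sample_id", "label") %in% names(samples)))
  n0 <- sum(samples$label == 0)
  n1 <- sum(samples$label == 1)
  if (n0 == 0 || n1 == 0) {
    stop("upsample_minority: both classes must be present", call. = FALSE)
  }
  minority <- if (n0 <= n1) 0L else 1L
  factor <- as.integer(round(max(n0, n1) / min(n0, n1)))
  base <- data.frame(sample_id = samples$sample_id,
                     label = as.integer(samples$label),
                     rep_index = 0L, stringsAsFactors = FALSE)
  if (factor <= 1) return(base)
  min_rows <- base[base$label == minority, ]
  reps <- do.call(rbind, lapply(seq_len(factor - 1L), function(r) {
    transform(min_rows, rep_index = r)
  }))
  out <- rbind(base, reps)
  rownames(out) <- NULL
  out
}

#' @export
#' @rdname upsample_minority
#' @param expanded An expanded sample table.
upsampling_factor <- function(expanded) {
  max(expanded$rep_index) + 1L
}

# ---- patch loading ---------------------------------------------------------

#' Load cohort patches (and masks) into memory
#'
#' Reads every patch of a manifest, optionally normalizing intensities
#' ([normalize_intensity()]), and optionally the ground-truth chiasm masks
#' written by [generate_cohort()].
#'
#' @param manifest Cohort manifest.
#' @param normalize Apply robust min-max normalization (default TRUE).
#' @param masks Also load `*_mask.nii.gz` sidecars (default FALSE).
#' @return A list: `patches` (named list of arrays by sample id), `labels`
#'   (named integer vector), and `masks` if requested.
#' @export
load_cohort_patches <- function(manifest, normalize = TRUE, masks = FALSE) {
  patches <- list()
  mk <- list()
  for (i in seq_len(nrow(manifest))) {
    arr <- read_volume(manifest$path[i])$voxels
    if (normalize) arr <- normalize_intensity(arr)
    patches[[manifest$sample_id[i]]] <- arr
    if (masks) {
      mk[[manifest$sample_id[i]]] <-
        read_volume(cohort_mask_path(manifest$path[i]))$voxels
    }
  }
  labels <- stats::setNames(as.integer(manifest$label), manifest$sample_id)
  out <- list(patches = patches, labels = labels)
  if (masks) out$masks <- mk
  out
}

#' Chiasm-excluded pretraining inputs
#'
#' Applies [mask_chiasm_out()] with the ground-truth masks to every patch
#' of a cohort — the autoencoder must learn everything *except* the
#' structure the classifier discriminates on, preventing leakage.
#'
#' @param cohort Output of [load_cohort_patches()] with `masks = TRUE`.
#' @param fill Fill strategy, see [mask_chiasm_out()].
#' @return Named list of chiasm-excluded patch arrays.
#' @export
chiasm_excluded_patches <- function(cohort, fill = "background_mean") {
  stopifnot(!is.null(cohort$masks))
  mapply(function(p, m) mask_chiasm_out(p, m, fill = fill),
         cohort$patches, cohort$masks[names(cohort$patches)],
         SIMPLIFY = FALSE)
}

# ---- autoencoder pretraining ----------------------------------------------

#' Pretrain the feature-extraction encoder as an autoencoder
#'
#' Minimizes voxelwise mean squared reconstruction error with Adam on
#' chiasm-excluded patches. A seeded holdout subset monitors
#' generalization; epoch 0 of the history records the pre-training holdout
#' loss.
#'
#' @param model A `chiasm_autoencoder` from [build_autoencoder()].
#' @param samples List of patch arrays (chiasm-excluded; see
#'   [chiasm_excluded_patches()]).
#' @param epochs,batch_size,lr Optimizer settings (Adam, defaults 15/32/1e-3).
#' @param holdout_fraction Fraction of samples held out for monitoring.
#' @param seed Seed controlling shuffling and batching.
#' @return A list: `model` (trained autoencoder), `encoder`
#'   ([get_encoder()] of it), `history` (data.frame `epoch`, `train_loss`,
#'   `dev_loss`).
#' @export
pretrain_autoencoder <- function(model, samples, epochs = 15,
                                 batch_size = 32, lr = 1e-3,
                                 holdout_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(model, "chiasm_autoencoder"))
  if (length(samples) == 0) {
    stop("pretrain_autoencoder: no samples supplied", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(samples)
  perm <- sample.int(n)
  n_hold <- max(1, min(n - 1, round(holdout_fraction * n)))
  if (n == 1) n_hold <- 0
  hold_idx <- if (n_hold > 0) perm[seq_len(n_hold)] else integer(0)
  train_idx <- setdiff(perm, hold_idx)
  X_hold <- if (n_hold > 0) .stack_patches(samples[hold_idx]) else NULL
  layers <- model$layers
  opt <- .adam_init(layers)
  hold_loss <- function(ls) {
    if (is.null(X_hold)) return(NA_real_)
    R <- .net_forward(ls, X_hold)$out
    mean((R - X_hold)^2)
  }
  history <- data.frame(epoch = 0, train_loss = NA_real_,
                        dev_loss = hold_loss(layers))
  for (epoch in seq_len(epochs)) {
    idx <- train_idx[sample.int(length(train_idx))]
    batch_losses <- c()
    for (start in seq(1, length(idx), by = batch_size)) {
      bidx <- idx[start:min(start + batch_size - 1, length(idx))]
      X <- .stack_patches(samples[bidx])
      fw <- .net_forward(layers, X, want_cache = TRUE)
      R <- fw$out
      diffs <- R - X
      batch_losses <- c(batch_losses, mean(diffs^2))
      dR <- 2 * diffs / length(diffs)
      bw <- .net_backward(layers, fw$caches, dR)
      stepped <- .adam_step(layers, bw$grads, opt, lr)
      layers <- stepped$layers
      opt <- stepped$opt
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = mean(batch_losses),
                                dev_loss = hold_loss(layers)))
  }
  model$layers <- layers
  list(model = model, encoder = get_encoder(model), history = history)
}

# ---- classifier fine-tuning ------------------------------------------------

# Assemble the (augmented) input batch for a set of row indices of an
# expanded sample table. Repetitions (rep_index > 0) receive an independent
# rigid-shift augmentation, re-drawn per epoch.
.augmented_batch <- function(rows, patches, augment_mm, seed, epoch) {
  arrs <- vector("list", nrow(rows))
  for (j in seq_len(nrow(rows))) {
    arr <- patches[[rows$sample_id[j]]]
    if (rows$rep_index[j] > 0 && any(augment_mm > 0)) {
      s <- .derive_seed(seed, epoch, j, rows$rep_index[j])
      old <- .Random.seed_save()
      set.seed(s)
      shift <- stats::runif(3, -1, 1) * augment_mm
      .Random.seed_restore(old)
      arr <- .shift_patch(arr, shift)
    }
    arrs[[j]] <- arr
  }
  .stack_patches(arrs)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fine-tune the classification head
#'
#' Trains the classifier with binary cross-entropy and Adam on an
#' upsampled TRAIN table, monitoring loss and AUROC on an upsampled
#' DEV_TRAIN table each epoch, and finally restores the weights of the
#' epoch chosen by [select_checkpoint()]. Minority repetitions get an
#' independent rigid-shift augmentation re-drawn every epoch (TRAIN) or
#' fixed once (DEV_TRAIN, for stable monitoring). The encoder is frozen by
#' default; set `freeze_encoder = FALSE` for end-to-end fine-tuning.
#'
#' @param model A `chiasm_classifier` from [build_classifier()].
#' @param train,dev Lists with elements `table` (data.frame `sample_id`,
#'   `label`, `rep_index`, e.g. from [upsample_minority()]) and `patches`
#'   (named list of arrays).
#' @param epochs,batch_size,lr Optimizer settings (defaults 15/32/1e-3).
#' @param seed Seed for shuffling, batching, augmentation.
#' @param criterion Checkpoint selection criterion, see
#'   [select_checkpoint()].
#' @param freeze_encoder Keep encoder weights fixed (default TRUE).
#' @param augment_mm Augmentation shift amplitudes (mm per axis).
#' @return A list: `model` (weights of the selected epoch), `history`
#'   (list with `records` data.frame `epoch`, `train_loss`, `dev_loss`,
#'   `dev_auroc` and `selected_epoch`).
#' @export
finetune_classifier <- function(model, train, dev, epochs = 15,
                                batch_size = 32, lr = 1e-3, seed = 1L,
                                criterion = "max_dev_auroc",
                                freeze_encoder = TRUE,
                                augment_mm = c(1.5, 1.5, 0.75)) {
  stopifnot(inherits(model, "chiasm_classifier"), model$kind == "cnn")
  if (length(unique(dev$table$label)) < 2) {
    stop("finetune_classifier: DEV set is single-class, cannot monitor",
         call. = FALSE)
  }
  if (epochs == 0) {
    return(list(model = model,
                history = list(records = data.frame(epoch = integer(0),
                                                    train_loss = numeric(0),
                                                    dev_loss = numeric(0),
                                                    dev_auroc = numeric(0)),
                               selected_epoch = NA_integer_)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  layers <- model$layers
  trainable <- rep(TRUE, length(layers))
  if (freeze_encoder) trainable[seq_len(model$n_encoder_layers)] <- FALSE
  opt <- .adam_init(layers)
  # dev batch fixed across epochs (repetitions augmented once, epoch tag 0)
  X_dev <- .augmented_batch(dev$table, dev$patches, augment_mm, seed, 0L)
  y_dev <- dev$table$label
  records <- NULL
  snapshots <- vector("list", epochs)
  tab <- train$table
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(nrow(tab))
    batch_losses <- c()
    for (start in seq(1, nrow(tab), by = batch_size)) {
      rows <- tab[ord[start:min(start + batch_size - 1, nrow(tab))], ,
                  drop = FALSE]
      X <- .augmented_batch(rows, train$patches, augment_mm, seed, epoch)
      y <- rows$label
      fw <- .net_forward(layers, X, want_cache = TRUE)
      p <- as.numeric(fw$out)
      batch_losses <- c(batch_losses, .bce(p, y))
      dZ <- matrix((p - y) / length(y), nrow = 1)
      bw <- .net_backward(layers, fw$caches, dZ, from = length(layers) - 1)
      stepped <- .adam_step(layers, bw$grads, opt, lr, trainable = trainable)
      layers <- stepped$layers
      opt <- stepped$opt
    }
    p_dev <- as.numeric(.net_forward(layers, X_dev)$out)
    rec <- data.frame(epoch = epoch - 1L,
                      train_loss = mean(batch_losses),
                      dev_loss = .bce(p_dev, y_dev),
                      dev_auroc = roc_and_auroc(p_dev, y_dev)$auroc)
    records <- rbind(records, rec)
    snapshots[[epoch]] <- layers
  }
  sel <- select_checkpoint(records, criterion)
  model$layers <- snapshots[[sel + 1L]]
  list(model = model,
       history = list(records = records, selected_epoch = sel))
}

#' Select the best training epoch
#'
#' Argmax of `dev_auroc` (`"max_dev_auroc"`) or argmin of `dev_loss`
#' (`"min_dev_loss"`); ties are broken toward the earliest epoch.
#'
#' @param history A history `records` data.frame (columns `epoch` plus the
#'   monitored quantity), a list with a `records` element, or a bare
#'   numeric vector (taken as per-epoch criterion values, epoch 0 first).
#' @param criterion `"max_dev_auroc"` or `"min_dev_loss"`.
#' @return The selected (0-based) epoch index.
#' @export
select_checkpoint <- function(history, criterion = c("max_dev_auroc",
                                                     "min_dev_loss")) {
  criterion <- match.arg(criterion)
  if (is.list(history) && !is.data.frame(history) &&
      !is.null(history$records)) {
    history <- history$records
  }
  if (is.data.frame(history)) {
    if (nrow(history) == 0) {
      stop("select_checkpoint: empty history", call. = FALSE)
    }
    vals <- if (criterion == "max_dev_auroc") history$dev_auroc
            else history$dev_loss
    epochs <- history$epoch
  } else {
    if (length(history) == 0) {
      stop("select_checkpoint: empty history", call. = FALSE)
    }
    vals <- as.numeric(history)
    epochs <- seq_along(vals) - 1L
  }
  idx <- if (criterion == "max_dev_auroc") which.max(vals)
         else which.min(vals)
  as.integer(epochs[idx])
}
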