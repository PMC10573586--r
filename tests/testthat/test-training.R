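# training: fold construction, upsampling, pretraining, fine-tuning,
# checkpoint selection.

# A path-free manifest stand-in (fold logic never touches files).
fake_manifest <- function(n_control, n_albinism, tags = c("a", "b", "c")) {
  n <- n_control + n_albinism
  data.frame(sample_id = sprintf("m%05d", seq_len(n)),
             path = "unused.nii.gz",
             label = rep(c(0L, 1L), c(n_control, n_albinism)),
             dataset_tag = rep_len(tags, n),
             cx = 0, cy = 0, cz = 0, stringsAsFactors = FALSE)
}

test_that("the paper-scale composition reproduces the printed group sizes", {
  man <- fake_manifest(1708, 32)
  splits <- make_fold_splits(man, k = 8, composition = paper_composition(),
                             seed = 3)
  expect_length(splits, 8)
  lab <- stats::setNames(man$label, man$sample_id)
  counts <- function(ids) c(sum(lab[ids] == 0), sum(lab[ids] == 1))
  sp <- splits[[1]]
  expect_equal(counts(sp$train_ids), c(1274, 23))
  expect_equal(counts(sp$dev_ids), c(216, 4))
  expect_equal(counts(sp$test1_ids), c(4, 4))
  expect_equal(counts(sp$test2_ids), c(214, 1))
  expect_equal(sp$upsampling_factor, 55L)

  in_test <- character(0)
  for (sp in splits) {
    all_ids <- c(sp$train_ids, sp$dev_ids, sp$test1_ids, sp$test2_ids)
    expect_equal(sort(all_ids), sort(man$sample_id)) # disjoint cover
    expect_length(intersect(c(sp$train_ids, sp$dev_ids),
                            c(sp$test1_ids, sp$test2_ids)), 0)
    in_test <- union(in_test, c(sp$test1_ids, sp$test2_ids))
  }
  # every sample held out at least once across the folds
  expect_setequal(in_test, man$sample_id)
})

test_that("toy two-fold split is exhaustively consistent", {
  man <- fake_manifest(4, 4, tags = "one")
  comp <- fold_composition(train = c(2, 2), dev = c(1, 1),
                           test1 = c(1, 1), test2 = c(0, 0))
  splits <- make_fold_splits(man, k = 2, composition = comp, seed = 1)
  for (sp in splits) {
    groups <- list(sp$train_ids, sp$dev_ids, sp$test1_ids, sp$test2_ids)
    expect_equal(sort(unlist(groups)), sort(man$sample_id))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_length(intersect(groups[[i]], groups[[j]]), 0)
    }
  }
  expect_error(
    make_fold_splits(man, k = 2, seed = 1,
                     composition = fold_composition(train = c(3, 3),
                                                    dev = c(1, 1),
                                                    test1 = c(1, 1),
                                                    test2 = c(0, 0))),
    "composition requires")
})

test_that("minority upsampling follows the matching-factor rule", {
  # the full-protocol TRAIN imbalance: round(1274/23) = 55
  big <- data.frame(sample_id = sprintf("s%04d", 1:1297),
                    label = rep(c(0L, 1L), c(1274, 23)))
  up <- upsample_minority(big)
  expect_equal(upsampling_factor(up), 55L)
  expect_equal(sum(up$label == 1), 23 * 55)

  balanced <- data.frame(sample_id = sprintf("b%02d", 1:20),
                         label = rep(0:1, each = 10))
  expect_identical(upsample_minority(balanced)$sample_id,
                   balanced$sample_id)

  small <- data.frame(sample_id = sprintf("c%02d", 1:9),
                      label = rep(c(0L, 1L), c(7, 2)))
  up2 <- upsample_minority(small)
  expect_equal(upsampling_factor(up2), 4L)
  expect_equal(sum(up2$label == 1), 8)
  expect_equal(sum(up2$label == 0), 7)
  # repetition only: the distinct minority ids are unchanged
  expect_setequal(unique(up2$sample_id[up2$label == 1]),
                  small$sample_id[small$label == 1])

  expect_error(upsample_minority(data.frame(sample_id = "x", label = 1L)),
               "both classes")
})

test_that("autoencoder pretraining reduces held-out loss deterministically", {
  samples <- lapply(fx$cohort$patches[1:24], identity)
  ae <- build_autoencoder(encoder_config(), seed = 14)
  out <- pretrain_autoencoder(ae, samples, epochs = 3, seed = 14)
  h <- out$history
  expect_lt(h$dev_loss[nrow(h)], h$dev_loss[1]) # epoch 0 = pre-training

  out2 <- pretrain_autoencoder(ae, samples, epochs = 3, seed = 14)
  expect_identical(out$history, out2$history)

  frozen <- pretrain_autoencoder(ae, samples, epochs = 2, lr = 0, seed = 1)
  expect_identical(frozen$model$layers, ae$layers)
  expect_equal(frozen$history$train_loss[2], frozen$history$train_loss[3])

  expect_error(pretrain_autoencoder(ae, list(), epochs = 1), "no samples")
})

test_that("fine-tuning honours the zero-epoch and monitoring contracts", {
  clf <- build_classifier(fx$encoder, seed = 15)
  tab <- data.frame(sample_id = fx$train_ids[c(1:6, 41:44)],
                    label = fx$cohort$labels[fx$train_ids[c(1:6, 41:44)]],
                    rep_index = 0L)
  tr <- list(table = tab, patches = fx$cohort$patches)

  fit0 <- finetune_classifier(clf, tr, tr, epochs = 0)
  expect_identical(fit0$model$layers, clf$layers)

  single <- tab[tab$label == 0, ]
  expect_error(finetune_classifier(clf, tr,
                                   list(table = single,
                                        patches = fx$cohort$patches),
                                   epochs = 1), "single-class")

  fit_a <- finetune_classifier(clf, tr, tr, epochs = 2, seed = 8)
  fit_b <- finetune_classifier(clf, tr, tr, epochs = 2, seed = 8)
  expect_identical(fit_a$history$records, fit_b$history$records)
})

test_that("checkpoint selection is an argmax/argmin with early-tie rule", {
  expect_identical(select_checkpoint(c(0.5, 0.9, 0.7)), 1L)
  expect_identical(select_checkpoint(c(0.5, 0.5, 0.5)), 0L)
  h <- data.frame(epoch = 0:2, dev_loss = c(0.4, 0.2, 0.3),
                  dev_auroc = c(0.6, 0.6, 0.9))
  expect_identical(select_checkpoint(h, "min_dev_loss"), 1L)
  expect_identical(select_checkpoint(h, "max_dev_auroc"), 2L)
  expect_error(select_checkpoint(numeric(0)), "empty")

  set.seed(16)
  vals <- round(runif(100), 3)
  got <- select_checkpoint(vals)
  # linear-scan oracle with the earliest-epoch tie rule
  best <- 0L
  for (e in seq_along(vals)) if (vals[e] > vals[best + 1L]) best <- e - 1L
  expect_identical(got, best)
})

test_that("separability is monotone in effect size (reduced-scale grid)", {
  # dev AUROC means (3 seeds, single split) across the effect-size grid
  # {0, 0.5x, 1x} of the default albinism effects; scaled down from the
  # 5-seed full-grid statement to stay within the CI budget
  grid_auroc <- function(scale, seed) {
    cfg <- phantom_effect_config(
      width_ratio = 1 - scale * (1 - 0.7),
      tract_angle_offset_deg = scale * 15,
      central_boost = scale * 0.15)
    dir <- file.path(tempdir(), sprintf("grid_%g_%d", scale, seed))
    unlink(dir, recursive = TRUE)
    man <- generate_cohort(24, 8, cfg, dir, seed = seed)
    co <- load_cohort_patches(man)
    ids <- man$sample_id
    tr_ids <- c(ids[1:16], ids[25:30])
    dv_ids <- c(ids[17:24], ids[31:32])
    tab <- function(v) upsample_minority(
      data.frame(sample_id = v, label = co$labels[v]))
    clf <- build_classifier(encoder_config(), seed = seed)
    fit <- finetune_classifier(clf,
                               list(table = tab(tr_ids),
                                    patches = co$patches),
                               list(table = tab(dv_ids),
                                    patches = co$patches),
                               epochs = 8, seed = seed,
                               freeze_encoder = FALSE)
    utils::tail(fit$history$records$dev_auroc, 1) # final epoch, unbiased
  }
  means <- vapply(c(0, 0.5, 1), function(scale) {
    mean(vapply(1:3, function(s) grid_auroc(scale, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(means[2] >= means[1] - 0.1)
  expect_true(means[3] >= means[2] - 0.1)
  expect_gt(means[3], means[1]) # strict rise from null to full effect
})
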