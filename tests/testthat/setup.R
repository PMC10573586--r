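# Shared expensive fixtures, built once per test run (all in-code; nothing
# is stored in the repository). `fx` holds a small strong-effect phantom
# cohort and a classifier fine-tuned on it, reused by the saliency
# finite-difference checks and the XAI acceptance tests.

fx <- new.env()

local({
  fx$strong_cfg <- phantom_effect_config(width_ratio = 0.6,
                                         tract_angle_offset_deg = 20,
                                         central_boost = 0.2,
                                         noise_sigma = 0.05)
  fx$dir <- file.path(tempdir(), "chiasm_fixture_cohort")
  fx$manifest <- generate_cohort(48, 12, fx$strong_cfg, fx$dir, seed = 424L)
  fx$cohort <- load_cohort_patches(fx$manifest, normalize = TRUE,
                                   masks = TRUE)

  ae <- build_autoencoder(encoder_config(), seed = 31L)
  pre <- pretrain_autoencoder(ae, chiasm_excluded_patches(fx$cohort),
                              epochs = 4, seed = 31L)
  fx$encoder <- pre$encoder

  # train on the first 40 controls + 10 albinism, hold out 8 + 2 as tests
  ctrl <- fx$manifest$sample_id[fx$manifest$label == 0]
  alb <- fx$manifest$sample_id[fx$manifest$label == 1]
  fx$train_ids <- c(ctrl[1:40], alb[1:10])
  fx$test_ids <- c(ctrl[41:48], alb[11:12])
  tab <- data.frame(sample_id = fx$train_ids,
                    label = fx$cohort$labels[fx$train_ids])
  tr <- upsample_minority(tab)
  clf <- build_classifier(fx$encoder, seed = 32L)
  fit <- finetune_classifier(clf,
                             train = list(table = tr,
                                          patches = fx$cohort$patches),
                             dev = list(table = tr,
                                        patches = fx$cohort$patches),
                             epochs = 8, seed = 32L,
                             freeze_encoder = FALSE)
  fx$model <- fit$model
})
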