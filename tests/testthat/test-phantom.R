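# phantom module: parameter sampling, rendering, noise, cohort generation.

test_that("parameter draws centre on population means and apply effects", {
  cfg <- quiet_config()
  p <- sample_phantom_params(0, cfg, seed = 5)
  expect_equal(p$body_width_mm, 15.0)
  expect_equal(p$body_height_mm, 3.5)
  expect_equal(p$central_boost, 0)

  # zero effect size: albinism draw equals the control draw
  null_cfg <- phantom_null_config(variation_cv = 0, noise_sigma = 0,
                                  vessel_probability = 0,
                                  jitter_translation_mm = c(0, 0, 0),
                                  jitter_rotation_deg = c(0, 0, 0))
  p0 <- sample_phantom_params(0, null_cfg, seed = 9)
  p1 <- sample_phantom_params(1, null_cfg, seed = 9)
  expect_equal(p1[setdiff(names(p1), "class_label")],
               p0[setdiff(names(p0), "class_label")])

  # width ratio applies multiplicatively
  p <- sample_phantom_params(1, quiet_config(width_ratio = 0.7), seed = 2)
  expect_equal(p$body_width_mm, 15.0 * 0.7)

  # determinism and invalid effects
  expect_identical(sample_phantom_params(1, cfg, seed = 77),
                   sample_phantom_params(1, cfg, seed = 77))
  expect_error(sample_phantom_params(1, quiet_config(width_ratio = 0),
                                     seed = 1), "invalid effect")
})

test_that("rendering produces the documented geometry", {
  cfg <- quiet_config()
  r <- render_phantom(sample_phantom_params(0, cfg, seed = 1))

  # zero contrast collapses to a constant patch
  flat_cfg <- quiet_config(bg_intensity = 0.5, wm_intensity = 0.5)
  rf <- render_phantom(sample_phantom_params(0, flat_cfg, seed = 1))
  expect_equal(diff(range(rf$patch$voxels)), 0)

  # chiasm width: mask extent along left-right at the central coronal plane
  for (yi in c(12, 13)) {
    extent <- sum(apply(r$mask[, yi, ], 1, max) > 0)
    expect_gte(extent, 14)
    expect_lte(extent, 16)
  }

  # narrower albinism chiasm has strictly fewer mask voxels
  ra <- render_phantom(sample_phantom_params(1, quiet_config(width_ratio = 0.7),
                                             seed = 1))
  expect_lt(sum(ra$mask), sum(r$mask))

  # deterministic given params
  p <- sample_phantom_params(1, phantom_effect_config(), seed = 3)
  expect_identical(render_phantom(p), render_phantom(p))

  # clipping names the violated face
  p_clip <- sample_phantom_params(0, cfg, seed = 1)
  p_clip$jitter_translation_mm <- c(0, 0, 3.5)
  expect_error(render_phantom(p_clip), "z-max")
})

test_that("mask voxel count is monotone in width_ratio over 20 seeds", {
  for (seed in 1:20) {
    n <- vapply(c(1, 0.8, 0.6), function(wr) {
      cfg <- phantom_effect_config(width_ratio = wr, variation_cv = 0.05,
                                   noise_sigma = 0, vessel_probability = 0,
                                   jitter_translation_mm = c(0, 0, 0),
                                   jitter_rotation_deg = c(0, 0, 0))
      sum(render_phantom(sample_phantom_params(1, cfg, seed = seed))$mask)
    }, numeric(1))
    expect_lt(n[2], n[1]) # width_ratio 0.8 strictly smaller at zero noise
    expect_lte(n[3], n[2])
  }
})

test_that("class contrast reproduces the expected sign pattern", {
  cfg <- phantom_effect_config(noise_sigma = 0)
  patches <- list()
  labels <- integer(0)
  for (i in 1:100) {
    lab <- as.integer(i > 50)
    r <- render_with_retry(lab, cfg, seed = 5000 + i * 13)
    patches[[i]] <- r$patch$voxels
    labels[i] <- lab
  }
  avg <- class_average_and_difference(patches, labels)
  ax <- seq_len(24) - 1 - 11.5
  az <- seq_len(8) - 1 - 3.5
  central <- abs(ax) < 2.5
  zmid <- abs(az) < 2
  # central crossing brighter in albinism
  expect_gt(mean(avg$diff_a_minus_c[central, central, zmid]), 0)
  # lateral chiasm/tract band brighter in controls
  lat <- abs(ax) >= 4 & abs(ax) <= 9
  expect_gt(mean(avg$diff_c_minus_a[lat, abs(ax) <= 4, zmid]), 0)
})

test_that("Rician noise has the right distribution and determinism", {
  z <- array(0, c(50, 50, 40)) # 1e5 voxels
  expect_identical(add_rician_noise(z, 0, seed = 1), z)
  out <- add_rician_noise(z, 1, seed = 2)
  expect_lt(abs(mean(out) - sqrt(pi / 2)) / sqrt(pi / 2), 0.01)

  # high SNR: Rician mean approximately the signal
  const <- array(100, c(24, 24, 8))
  expect_lt(abs(mean(add_rician_noise(const, 0.1, seed = 3)) - 100.0001),
            0.01)

  expect_identical(add_rician_noise(z, 0.3, seed = 9),
                   add_rician_noise(z, 0.3, seed = 9))
  expect_error(add_rician_noise(z, -1), "non-negative")
})

test_that("cohort generation writes a reproducible, well-formed cohort", {
  dir_a <- file.path(tempdir(), "coh_a")
  dir_b <- file.path(tempdir(), "coh_b")
  unlink(c(dir_a, dir_b), recursive = TRUE)
  man_a <- generate_cohort(4, 4, phantom_effect_config(), dir_a, seed = 7)
  man_b <- generate_cohort(4, 4, phantom_effect_config(), dir_b, seed = 7)

  expect_equal(nrow(man_a), 8)
  expect_equal(sum(man_a$label == 0), 4)
  expect_equal(sum(man_a$label == 1), 4)

  # reproducibility: identical manifests (up to directory) and voxels
  norm <- function(m) transform(m, path = basename(path))
  expect_identical(norm(man_a), norm(man_b))
  for (i in c(1, 5, 8)) {
    expect_identical(read_volume(man_a$path[i])$voxels,
                     read_volume(man_b$path[i])$voxels)
  }

  # sidecars exist and truth params reload
  expect_true(all(file.exists(cohort_mask_path(man_a$path))))
  tr <- read_phantom_truth(cohort_truth_path(man_a$path[5]))
  expect_s3_class(tr, "chiasm_phantom_params")
  expect_equal(tr$class_label, 1L)

  expect_error(generate_cohort(0, 0, out_dir = tempfile()), "empty cohort")
})

test_that("extreme imbalance generation matches the protocol ratio", {
  dir_c <- file.path(tempdir(), "coh_imb")
  unlink(dir_c, recursive = TRUE)
  man <- generate_cohort(214, 1, phantom_effect_config(), dir_c, seed = 1)
  expect_equal(as.numeric(table(man$label)), c(214, 1))
})

test_that("embed/extract round-trips exactly", {
  patch <- random_patch(3)
  # identity embedding: volume of exactly patch size, centred
  v <- embed_patch_in_volume(patch, volume_dims_mm = c(24, 24, 8),
                             center_world_mm = c(12, 12, 4))
  expect_identical(v$voxels, patch)

  v2 <- embed_patch_in_volume(patch, c(64, 64, 32), c(30, 28, 15))
  back <- extract_patch(v2, c(30, 28, 15))
  expect_identical(back$voxels, patch)

  # extraction at an offset centre differs exactly in the shifted voxels
  off <- extract_patch(v2, c(33, 28, 15))
  expect_false(identical(off$voxels, patch))
  expect_identical(off$voxels[1:21, , ], patch[4:24, , ])

  expect_error(embed_patch_in_volume(patch, c(20, 20, 8), c(10, 10, 4)),
               "overflows")
})
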