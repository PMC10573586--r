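# explain: saliency, gradient-x-input, occlusion, localization, class
# averages. Closed-form models (constant, linear) provide exact oracles.

test_that("saliency obeys the closed-form and finite-difference oracles", {
  x <- random_patch(81)
  # input-independent model: zero map
  expect_equal(saliency_map(constant_score_model(0.7), x)$values,
               array(0, dim(x)))

  # linear functional: gradient = w * sigmoid'(w.x + b) exactly
  set.seed(82)
  w <- array(rnorm(4608, 0, 0.01), dim(x))
  lm <- linear_score_model(w, bias = 0.3)
  s <- predict_score(lm, x)
  m <- saliency_map(lm, x)
  expect_equal(m$values, w * s * (1 - s), tolerance = 1e-12)
  expect_equal(saliency_map(lm, x, signed = FALSE)$values,
               abs(m$values), tolerance = 1e-12)

  # finite differences on the linear model
  h <- 1e-3
  for (i in list(c(3, 4, 2), c(20, 11, 7))) {
    xp <- x; xp[i[1], i[2], i[3]] <- xp[i[1], i[2], i[3]] + h
    xm <- x; xm[i[1], i[2], i[3]] <- xm[i[1], i[2], i[3]] - h
    fd <- (predict_score(lm, xp) - predict_score(lm, xm)) / (2 * h)
    expect_equal(m$values[i[1], i[2], i[3]], fd, tolerance = 1e-4)
  }
})

test_that("saliency of the trained model matches central differences", {
  id <- fx$test_ids[1]
  x <- fx$cohort$patches[[id]]
  m <- saliency_map(fx$model, x)
  h <- 1e-3
  set.seed(83)
  checked <- 0
  for (rep in 1:40) {
    i <- sample(24, 1); j <- sample(24, 1); k <- sample(8, 1)
    xp <- x; xp[i, j, k] <- xp[i, j, k] + h
    xm <- x; xm[i, j, k] <- xm[i, j, k] - h
    fd <- (predict_score(fx$model, xp) - predict_score(fx$model, xm)) /
      (2 * h)
    if (abs(fd) < 1e-7) next # relative error undefined near zero
    expect_lt(abs(m$values[i, j, k] - fd) / abs(fd), 1e-3)
    checked <- checked + 1
    if (checked >= 20) break
  }
  expect_gte(checked, 20)
})

test_that("gradient-x-input satisfies zero and completeness properties", {
  z <- array(0, c(24, 24, 8))
  expect_equal(gradient_x_input(fx$model, z)$values, z)
  expect_equal(gradient_x_input(constant_score_model(), random_patch(1))$values,
               z)

  # linear-model completeness: sum of attributions equals
  # sigmoid'(z) * (z - b), the input's exact contribution to the logit
  set.seed(84)
  w <- array(rnorm(4608, 0, 0.01), c(24, 24, 8))
  lm <- linear_score_model(w, bias = 0.1)
  x <- random_patch(85)
  gxi <- gradient_x_input(lm, x)
  zlogit <- sum(w * x) + 0.1
  s <- plogis(zlogit)
  expect_equal(sum(gxi$values), s * (1 - s) * (zlogit - 0.1),
               tolerance = 1e-10)
})

test_that("occlusion matches the additive-model oracle", {
  x <- random_patch(86)
  expect_equal(occlusion_map(constant_score_model(), x)$values,
               array(0, dim(x)))

  # additive (linear) model, window == stride, zero fill: each voxel's
  # attribution is the score drop from removing exactly its own window
  w <- array(0.005, c(24, 24, 8))
  lm <- linear_score_model(w, bias = -1)
  spec <- occlusion_spec(window_voxels = c(4, 4, 2),
                         stride_voxels = c(4, 4, 2), fill = "zero")
  amap <- occlusion_map(lm, x, spec)
  base <- predict_score(lm, x)
  for (g in list(c(1, 1, 1), c(5, 9, 3), c(21, 21, 7))) {
    win_sum <- sum(x[g[1]:(g[1] + 3), g[2]:(g[2] + 3), g[3]:(g[3] + 1)])
    want <- base - plogis(sum(w * x) - 0.005 * win_sum - 1)
    expect_equal(amap$values[g[1], g[2], g[3]], want, tolerance = 1e-12)
  }

  # a model that ignores a region attributes exactly zero there
  w2 <- w
  w2[1:8, 1:8, ] <- 0
  amap2 <- occlusion_map(linear_score_model(w2), x, spec)
  expect_equal(amap2$values[1:8, 1:8, ], array(0, c(8, 8, 8)))

  # degenerate spec: one full-patch window, same delta everywhere
  full <- occlusion_spec(window_voxels = c(24, 24, 8),
                         stride_voxels = c(1, 1, 1), fill = "zero")
  amap3 <- occlusion_map(lm, x, full)
  expect_equal(length(unique(as.vector(amap3$values))), 1L)
  expect_equal(amap3$values[1], base - predict_score(lm, array(0, dim(x))))

  expect_error(occlusion_spec(window_voxels = c(30, 4, 2)), "exceeds")
})

test_that("localization score honours its tie and null behaviour", {
  d <- c(24, 24, 8)
  mask <- array(0L, d)
  mask[8:17, 8:17, 2:6] <- 1L # 500 voxels > the 230-voxel top-5% cut

  inside_only <- array(0, d)
  inside_only[mask == 1] <- runif(sum(mask))
  expect_equal(localization_score(inside_only, mask, 0.05), 1)

  # all-equal map: deterministic via the index-order tie rule
  flat <- array(1, d)
  m <- floor(0.05 * prod(d))
  expect_equal(localization_score(flat, mask, 0.05),
               mean(mask[seq_len(m)] > 0))

  # uniform random maps recover the mask volume fraction on average
  mask10 <- array(0L, d)
  mask10[seq_len(round(0.10 * prod(d)))] <- 1L
  set.seed(87)
  sc <- replicate(300, localization_score(array(runif(prod(d)), d),
                                          mask10, 0.05))
  expect_lt(abs(mean(sc) - 0.10), 0.01)

  expect_error(localization_score(flat, array(0L, d)), "empty mask")
})

test_that("class averages and threshold masks behave as documented", {
  ps <- lapply(1:6, random_patch)
  same <- class_average_and_difference(c(ps[1:3], ps[1:3]),
                                       c(0, 0, 0, 1, 1, 1))
  expect_equal(same$diff_c_minus_a, array(0, c(24, 24, 8)))

  mixed <- class_average_and_difference(ps, c(0, 1, 0, 1, 0, 1))
  expect_identical(mixed$diff_c_minus_a, -mixed$diff_a_minus_c)
  expect_error(class_average_and_difference(ps, rep(1, 6)), "both classes")

  avg <- mixed$avg_control
  tm <- threshold_mask(avg, 0.75)
  expect_identical(dim(tm), dim(avg))
  expect_equal(sum(tm), sum(avg < 0.75))
  expect_true(all(avg[tm == 1] < 0.75))
  expect_identical(threshold_mask(avg, min(avg) - 1),
                   array(0L, dim(avg)))
})

test_that("attribution maps export as NIfTI next to their patch", {
  amap <- saliency_map(fx$model, fx$cohort$patches[[fx$test_ids[1]]])
  f <- tempfile(fileext = ".nii.gz")
  write_attribution(amap, f)
  v <- read_volume(f)
  expect_identical(dim(v$voxels), c(24L, 24L, 8L))
  expect_equal(v$voxels, amap$values, tolerance = 1e-6)
  expect_equal(v$affine[1:3, 4], c(-11.5, -11.5, -3.5))
})
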