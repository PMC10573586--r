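# data_io: NIfTI round-trips (incl. a nibabel cross-check), patch
# extraction, normalization, chiasm exclusion, manifests.

test_that("NIfTI volumes round-trip losslessly", {
  set.seed(11)
  arr <- array(runif(20 * 18 * 6), c(20, 18, 6))
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- c(-5, 3.5, 1.25)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(volume(arr, aff), f)
  v <- read_volume(f)
  expect_equal(v$voxels, arr, tolerance = 1e-6) # float32 storage
  expect_identical(v$affine, aff)               # affine stored exactly

  f2 <- tempfile(fileext = ".nii") # uncompressed path
  write_volume(volume(arr, aff), f2)
  expect_equal(read_volume(f2)$voxels, arr, tolerance = 1e-6)

  expect_error(read_volume(tempfile()), "not found")
  bad <- tempfile()
  writeLines("not a nifti at all, just text padding to be long enough",
             bad)
  expect_error(read_volume(bad), "NIfTI")
})

test_that("our NIfTI writer/reader agrees with nibabel", {
  # nibabel (Python, same image) is the independent format oracle
  py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(12)
  arr <- array(round(runif(10 * 12 * 6), 4), c(10, 12, 6))
  aff <- diag(4)
  aff[1:3, 4] <- c(-4.5, -5.5, -2.5)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(volume(arr, aff), f)
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy as np;",
    "img = nibabel.load('", f, "');",
    "d = np.asarray(img.dataobj);",
    "print(d.shape[0], d.shape[1], d.shape[2],",
    "      float(d.sum()), float(img.affine[0,3]))"
  ))), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1:3], dim(arr))
  expect_equal(vals[4], sum(arr), tolerance = 1e-4)
  expect_equal(vals[5], -4.5)

  # and the reverse: a file written by nibabel reads back identically
  g <- tempfile(fileext = ".nii.gz")
  system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy as np;",
    "a = np.arange(24, dtype=np.float32).reshape(2,3,4, order='F');",
    "nibabel.save(nibabel.Nifti1Image(a, np.diag([1.,1.,1.,1.])), '", g,
    "')"
  ))))
  v <- read_volume(g)
  expect_equal(as.vector(v$voxels), as.numeric(0:23))
})

test_that("patches written by the cohort generator load with patch shape", {
  expect_identical(dim(read_volume(fx$manifest$path[1])$voxels),
                   c(24L, 24L, 8L))
})

test_that("extract_patch matches the index-arithmetic oracle", {
  set.seed(21)
  for (rep in 1:5) {
    vox <- array(rnorm(40 * 36 * 20), c(40, 36, 20))
    vol <- volume(vox, diag(4))
    centre <- c(sample(12:28, 1), sample(12:24, 1), sample(4:16, 1))
    got <- extract_patch(vol, centre)
    expect_identical(dim(got$voxels), c(24L, 24L, 8L))
    expect_equal(got$voxels, oracle_extract(vox, centre, c(24L, 24L, 8L)))
  }
  # degenerate placements
  small <- volume(array(1, c(24, 24, 8)), diag(4))
  expect_error(extract_patch(small, c(0, 0, 0)), "outside the window|25%")
  expect_error(extract_patch(small, c(100, 0, 0)), "outside the volume")
})

test_that("non-isotropic volumes are resampled trilinearly", {
  # linear field: trilinear interpolation is exact, so values must match
  # the analytic field at the patch grid positions
  dims <- c(30, 30, 20)
  aff <- diag(c(2, 2, 2, 1)) # 2 mm spacing
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   k = 0:(dims[3] - 1))
  world <- cbind(2 * g$i, 2 * g$j, 2 * g$k)
  vox <- array(0.3 * world[, 1] + 0.2 * world[, 2] - 0.1 * world[, 3],
               dims)
  centre <- c(30, 30, 20)
  got <- extract_patch(volume(vox, aff), centre)
  ax <- list(seq_len(24) - 1 - 11.5, seq_len(24) - 1 - 11.5,
             seq_len(8) - 1 - 3.5)
  expected <- array(0, c(24, 24, 8))
  for (i in 1:24) for (j in 1:24) for (k in 1:8) {
    w <- centre + c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
    expected[i, j, k] <- 0.3 * w[1] + 0.2 * w[2] - 0.1 * w[3]
  }
  expect_equal(got$voxels, expected, tolerance = 1e-10)
})

test_that("normalization contract: range, idempotence, affine invariance", {
  const <- array(3, c(24, 24, 8))
  expect_identical(normalize_intensity(const), array(0, c(24, 24, 8)))

  ramp <- array(seq(0, 100, length.out = 4608), c(24, 24, 8))
  nr <- normalize_intensity(ramp)
  expect_equal(min(nr), 0)
  expect_equal(max(nr), 1)

  x <- random_patch(31)
  n1 <- normalize_intensity(x)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_equal(normalize_intensity(n1), n1, tolerance = 1e-12)
  expect_equal(normalize_intensity(2.5 * x + 7), n1, tolerance = 1e-12)
})

test_that("chiasm exclusion only touches masked voxels", {
  r <- render_with_retry(0, phantom_effect_config(), seed = 61)
  patch <- r$patch$voxels
  mask <- r$mask

  expect_identical(mask_chiasm_out(patch, array(0L, dim(patch))), patch)
  expect_identical(mask_chiasm_out(patch, array(1L, dim(patch)),
                                   fill = "zero"),
                   array(0, dim(patch)))

  out <- mask_chiasm_out(patch, mask, fill = "background_mean")
  expect_identical(out[mask == 0], patch[mask == 0])
  expect_lt(abs(mean(out[mask == 1]) - mean(patch[mask == 0])), 1e-6)
  expect_identical(mask_chiasm_out(patch, mask, "zero")[mask == 1],
                   rep(0, sum(mask)))

  expect_error(mask_chiasm_out(patch, array(0L, c(2, 2, 2))), "shape")
})

test_that("manifest round-trip and validation", {
  f <- tempfile(fileext = ".csv")
  save_manifest(fx$manifest, f)
  back <- load_manifest(f)
  expect_identical(back$sample_id, fx$manifest$sample_id)
  expect_identical(back$label, as.integer(fx$manifest$label))
  expect_identical(back[c("cx", "cy", "cz")],
                   fx$manifest[c("cx", "cy", "cz")])

  bad <- fx$manifest
  bad$label[3] <- 2
  save_manifest(bad, f)
  expect_error(load_manifest(f), "label not in \\{0,1\\}.*3")

  dup <- fx$manifest
  dup$sample_id[2] <- dup$sample_id[1]
  save_manifest(dup, f)
  expect_error(load_manifest(f), "duplicate")

  # the full-protocol TRAIN-group composition loads with correct counts
  big <- data.frame(sample_id = sprintf("t%04d", 1:1297),
                    path = "unused.nii.gz",
                    label = rep(c(0L, 1L), c(1274, 23)),
                    dataset_tag = "synthetic", cx = 0, cy = 0, cz = 0)
  save_manifest(big, f)
  loaded <- load_manifest(f, check_paths = FALSE)
  expect_equal(as.numeric(table(loaded$label)), c(1274, 23))
})
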