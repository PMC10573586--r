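# Synthetic chiasm phantom generator.
#
# Renders T1w-like 24x24x8 mm patches containing an X-shaped white-matter
# structure (two optic nerves converging anteriorly on a central chiasm body,
# two optic tracts diverging posteriorly) with class-dependent morphology:
# albinism draws a narrower chiasm/nerves, wider tract angles and a brighter
# central crossing than controls. Known ground truth (parameters + voxel
# mask) makes every downstream stage testable without clinical data.

#' Default effect configuration for phantom sampling
#'
#' Control means place the chiasm body at its population-average 15.0 mm
#' width and 3.5 mm height. Albinism effects (all tunable): chiasm/nerve
#' width multiplied by `width_ratio`, optic tract half-angle increased by
#' `tract_angle_offset_deg`, and a `central_boost` intensity increment at
#' the crossing. Between-subject variation is a coefficient of variation
#' applied to each morphometric draw. Intensities live on a [0,1] T1w-like
#' scale (background 0.35, white matter 0.75, vessel 0.9); noise is Rician.
#'
#' @param width_ratio Albinism chiasm/nerve width multiplier (>0, default 0.7).
#' @param tract_angle_offset_deg Albinism tract half-angle increment
#'   (degrees, default 15).
#' @param central_boost Albinism central intensity increment (default 0.15).
#' @param variation_cv Between-subject coefficient of variation (default 0.05).
#' @param noise_sigma Rician noise scale (default 0.05).
#' @param noise_model `"rician"` (magnitude MRI) or `"gaussian"`.
#' @param vessel_probability Probability of a vessel distractor (default 0.3).
#' @param jitter_translation_mm Translation jitter amplitudes per axis
#'   (uniform in +/- amplitude); default `c(2, 2, 1)` (only ~2 mm slack on
#'   the 8 mm inferior-superior axis).
#' @param jitter_rotation_deg Rotation jitter amplitudes per axis (default 5).
#' @param bg_intensity,wm_intensity,vessel_intensity Intensity levels in [0,1].
#' @param edge_width_mm Partial-volume smoothing scale (default 0.7).
#' @param boost_sd_mm Spatial scale of the central intensity bump (default 3).
#' @return A named list used by [sample_phantom_params()].
#' @export
phantom_effect_config <- function(width_ratio = 0.7,
                                  tract_angle_offset_deg = 15,
                                  central_boost = 0.15,
                                  variation_cv = 0.05,
                                  noise_sigma = 0.05,
                                  noise_model = c("rician", "gaussian"),
                                  vessel_probability = 0.3,
                                  jitter_translation_mm = c(2, 2, 1),
                                  jitter_rotation_deg = c(5, 5, 5),
                                  bg_intensity = 0.35,
                                  wm_intensity = 0.75,
                                  vessel_intensity = 0.9,
                                  edge_width_mm = 0.7,
                                  boost_sd_mm = 3) {
  list(
    control = list(body_width_mm = 15.0, body_height_mm = 3.5,
                   nerve_radius_mm = 1.75, tract_half_angle_deg = 35),
    width_ratio = width_ratio,
    tract_angle_offset_deg = tract_angle_offset_deg,
    central_boost = central_boost,
    variation_cv = variation_cv,
    noise_sigma = noise_sigma,
    noise_model = match.arg(noise_model),
    vessel_probability = vessel_probability,
    jitter_translation_mm = jitter_translation_mm,
    jitter_rotation_deg = jitter_rotation_deg,
    bg_intensity = bg_intensity,
    wm_intensity = wm_intensity,
    vessel_intensity = vessel_intensity,
    edge_width_mm = edge_width_mm,
    boost_sd_mm = boost_sd_mm
  )
}

#' Zero-effect configuration (null phantoms)
#'
#' Albinism multipliers/offsets set to identity/zero so both classes are
#' drawn from the control distribution; used for null-calibration runs.
#'
#' @param ... Passed on to [phantom_effect_config()].
#' @return An effect configuration list.
#' @export
phantom_null_config <- function(...) {
  phantom_effect_config(width_ratio = 1, tract_angle_offset_deg = 0,
                        central_boost = 0, ...)
}

#' Draw ground-truth parameters for one phantom
#'
#' Control draws centre on the population means (body width 15.0 mm, height
#' 3.5 mm); albinism draws apply the configured width ratio, tract-angle
#' offset and central boost. Jitter, vessel presence and all morphometric
#' variation are resolved here so that [render_phantom()] is deterministic
#' given the returned parameters.
#'
#' @param class_label 0 (control) or 1 (albinism).
#' @param effect_config See [phantom_effect_config()].
#' @param seed Integer seed; identical arguments give identical draws.
#' @return A `chiasm_phantom_params` list.
#' @export
sample_phantom_params <- function(class_label,
                                  effect_config = phantom_effect_config(),
                                  seed = 1L) {
  stopifnot(class_label %in% c(0, 1))
  cfg <- effect_config
  if (!is.numeric(cfg$width_ratio) || cfg$width_ratio <= 0) {
    stop("sample_phantom_params: invalid effect: width_ratio must be > 0",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  cv <- cfg$variation_cv
  vary <- function(mean) mean * (1 + cv * stats::rnorm(1))
  alb <- class_label == 1
  wr <- if (alb) cfg$width_ratio else 1
  body_width <- vary(cfg$control$body_width_mm * wr)
  body_height <- vary(cfg$control$body_height_mm)
  nerve_radius <- vary(cfg$control$nerve_radius_mm * wr)
  angle_mean <- cfg$control$tract_half_angle_deg +
    (if (alb) cfg$tract_angle_offset_deg else 0)
  tract_angle <- vary(angle_mean)
  boost <- if (alb && cfg$central_boost > 0) {
    max(0, vary(cfg$central_boost))
  } else if (alb) cfg$central_boost else 0
  jt <- stats::runif(3, -1, 1) * cfg$jitter_translation_mm
  jr <- stats::runif(3, -1, 1) * cfg$jitter_rotation_deg
  vessel_present <- stats::runif(1) < cfg$vessel_probability
  vessel_corner <- sample.int(4L, 1L)

  if (body_width <= 0) {
    stop("sample_phantom_params: invalid effect: resulting width <= 0",
         call. = FALSE)
  }
  params <- structure(list(
    class_label = as.integer(class_label),
    body_width_mm = body_width,
    body_height_mm = body_height,
    nerve_radius_mm = nerve_radius,
    tract_half_angle_deg = tract_angle,
    central_boost = boost,
    boost_sd_mm = cfg$boost_sd_mm,
    wm_intensity = cfg$wm_intensity,
    bg_intensity = cfg$bg_intensity,
    vessel_intensity = cfg$vessel_intensity,
    edge_width_mm = cfg$edge_width_mm,
    noise_sigma = cfg$noise_sigma,
    noise_model = cfg$noise_model,
    vessel_probability = cfg$vessel_probability,
    vessel_present = vessel_present,
    vessel_corner = as.integer(vessel_corner),
    jitter_translation_mm = jt,
    jitter_rotation_deg = jr,
    seed = as.integer(seed)
  ), class = "chiasm_phantom_params")
  .validate_phantom_params(params)
  params
}

.validate_phantom_params <- function(p) {
  stopifnot(p$body_width_mm > 0, p$body_height_mm > 0, p$nerve_radius_mm > 0,
            p$tract_half_angle_deg >= 0, p$tract_half_angle_deg < 90,
            p$central_boost >= 0, p$noise_sigma >= 0,
            p$wm_intensity >= 0, p$wm_intensity <= 1,
            p$bg_intensity >= 0, p$bg_intensity <= 1,
            p$vessel_intensity >= 0, p$vessel_intensity <= 1)
  invisible(p)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Signed distance (mm) from points u (3 x n) to a capsule (segment + radius).
.capsule_distance <- function(u, p0, p1, radius) {
  ab <- p1 - p0
  denom <- sum(ab^2)
  dx <- u[1, ] - p0[1]; dy <- u[2, ] - p0[2]; dz <- u[3, ] - p0[3]
  t <- if (denom > 0) {
    pmin(1, pmax(0, (dx * ab[1] + dy * ab[2] + dz * ab[3]) / denom))
  } else 0
  rx <- dx - t * ab[1]; ry <- dy - t * ab[2]; rz <- dz - t * ab[3]
  sqrt(rx^2 + ry^2 + rz^2) - radius
}

# C1 smoothstep of the signed distance: 1 deep inside, 0 outside, exactly
# 0.5 on the capsule surface (so mask = weight > 0.5 equals distance < 0).
.edge_weight <- function(d, edge_width) {
  t <- pmin(1, pmax(0, (edge_width - d) / (2 * edge_width)))
  t * t * (3 - 2 * t)
}

# Fixed (non-pathological) geometry constants of the X-shape, in mm.
.CHIASM_NERVE_HALF_ANGLE <- 25
.CHIASM_LIMB_LENGTH <- 6.0
.CHIASM_LIMB_X0 <- 2.5
.CHIASM_LIMB_Y0 <- 1.0

#' Render a phantom patch and its ground-truth chiasm mask
#'
#' Deterministically renders the noiseless intensity field of a phantom:
#' background plus an X-shaped union of four capsules (nerves, tracts)
#' around a central body, partial-volume smoothed over `edge_width_mm`, a
#' Gaussian central-crossing intensity bump of amplitude `central_boost`,
#' an optional vessel-like distractor capsule, all under the rigid jitter
#' stored in `params`. Noise is *not* added here; see [add_rician_noise()].
#'
#' @param params A `chiasm_phantom_params` from [sample_phantom_params()].
#' @param geometry The patch geometry (fixed; see [patch_geometry()]).
#' @return A list: `patch` (a [patch_volume()]) and `mask` (integer array,
#'   1 where the noiseless chiasm tissue weight exceeds 0.5).
#' @export
render_phantom <- function(params, geometry = patch_geometry()) {
  .validate_phantom_params(params)
  d <- geometry$dims
  ax <- .patch_axis_coords()
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  v <- t(as.matrix(g)) # 3 x n world mm, patch frame

  # jitter = rigid transform applied to the structure; sample the canonical
  # field at the inverse-transformed voxel positions
  R <- .rotation_matrix(params$jitter_rotation_deg)
  u <- solve(R) %*% (v - params$jitter_translation_mm)

  bw2 <- params$body_width_mm / 2
  bh2 <- params$body_height_mm / 2
  nr <- params$nerve_radius_mm
  na <- .CHIASM_NERVE_HALF_ANGLE * pi / 180
  ta <- params$tract_half_angle_deg * pi / 180
  L <- .CHIASM_LIMB_LENGTH
  x0 <- .CHIASM_LIMB_X0
  y0 <- .CHIASM_LIMB_Y0

  dist <- .capsule_distance(u, c(-(bw2 - bh2), 0, 0), c(bw2 - bh2, 0, 0), bh2)
  for (s in c(-1, 1)) {
    nerve <- .capsule_distance(
      u, c(s * x0, y0, 0),
      c(s * (x0 + L * sin(na)), y0 + L * cos(na), 0), nr)
    tract <- .capsule_distance(
      u, c(s * x0, -y0, 0),
      c(s * (x0 + L * sin(ta)), -y0 - L * cos(ta), 0), nr)
    dist <- pmin(dist, nerve, tract)
  }
  w <- .edge_weight(dist, params$edge_width_mm)
  mask <- array(as.integer(w > 0.5), dim = d)

  .check_mask_inside(mask, d)

  field <- params$bg_intensity +
    (params$wm_intensity - params$bg_intensity) * w
  if (params$central_boost > 0) {
    r2 <- colSums(u^2)
    field <- field +
      params$central_boost * exp(-r2 / (2 * params$boost_sd_mm^2)) * w
  }
  if (isTRUE(params$vessel_present)) {
    corner <- list(c(8.5, 8.5), c(-8.5, 8.5), c(-8.5, -8.5),
                   c(8.5, -8.5))[[params$vessel_corner]]
    dv <- .capsule_distance(u, c(corner, -6), c(corner, 6), 1)
    wv <- .edge_weight(dv, params$edge_width_mm)
    field <- field * (1 - wv) + params$vessel_intensity * wv
  }
  field <- pmin(1, pmax(0, field))
  list(patch = patch_volume(array(field, dim = d),
                            sample_id = paste0("phantom_seed", params$seed)),
       mask = mask)
}

.check_mask_inside <- function(mask, d) {
  faces <- list(
    "x-min" = mask[1, , ], "x-max" = mask[d[1], , ],
    "y-min" = mask[, 1, ], "y-max" = mask[, d[2], ],
    "z-min" = mask[, , 1], "z-max" = mask[, , d[3]]
  )
  hit <- names(faces)[vapply(faces, function(f) any(f > 0), logical(1))]
  if (length(hit)) {
    stop("render_phantom: structure clipped at patch face(s): ",
         paste(hit, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Add Rician (magnitude-MRI) noise
#'
#' `out = sqrt((x + n1)^2 + n2^2)` with `n1`, `n2` independent zero-mean
#' Gaussians of standard deviation `sigma` — the noise distribution of
#' magnitude MR images. On zero signal the output is Rayleigh with mean
#' `sigma * sqrt(pi/2)`; at high SNR it approaches additive Gaussian noise.
#'
#' @param patch A [patch_volume()] or bare array.
#' @param sigma Noise scale, `>= 0`; 0 returns the input unchanged.
#' @param seed Integer seed for reproducibility.
#' @return Same type as `patch`, with noisy voxels.
#' @export
add_rician_noise <- function(patch, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("add_rician_noise: sigma must be a non-negative scalar",
         call. = FALSE)
  }
  if (sigma == 0) return(patch)
  x <- .patch_array(patch)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(x)
  n1 <- stats::rnorm(n, 0, sigma)
  n2 <- stats::rnorm(n, 0, sigma)
  out <- array(sqrt((as.vector(x) + n1)^2 + n2^2), dim = dim(x))
  .with_patch_array(patch, out)
}

# Additive Gaussian alternative, used when effect_config$noise_model is
# "gaussian".
.add_gaussian_noise <- function(patch, sigma, seed = 1L) {
  if (sigma == 0) return(patch)
  x <- .patch_array(patch)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- x + array(stats::rnorm(length(x), 0, sigma), dim = dim(x))
  .with_patch_array(patch, out)
}

# Deterministic per-sample sub-seed derivation, kept below 2^31.
.derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p) %% 2147483629
  as.integer(s)
}

#' Generate a synthetic cohort on disk
#'
#' Renders `n_control + n_albinism` phantom patches, adds noise, and writes
#' each as NIfTI (`.nii.gz`, 1 mm isotropic, world origin at the patch
#' centre) together with a ground-truth chiasm mask NIfTI and a JSON truth
#' sidecar, plus a `manifest.csv`. Dataset tags are assigned round-robin
#' within each class to emulate multi-source data. Draws whose jittered
#' structure would clip the patch boundary are deterministically redrawn
#' with a derived sub-seed, so the output is fully reproducible under
#' `seed`.
#'
#' @param n_control,n_albinism Sample counts (`>= 0`, not both 0).
#' @param effect_config See [phantom_effect_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param dataset_tags Character vector of tags cycled over within class.
#' @return The manifest as a data.frame (invisibly written to
#'   `out_dir/manifest.csv`); columns `sample_id, path, label, dataset_tag,
#'   cx, cy, cz`.
#' @export
generate_cohort <- function(n_control, n_albinism,
                            effect_config = phantom_effect_config(),
                            out_dir = tempfile("cohort"),
                            seed = 1L,
                            dataset_tags = c("siteA", "siteB", "siteC")) {
  stopifnot(n_control >= 0, n_albinism >= 0)
  if (n_control + n_albinism == 0) {
    stop("generate_cohort: empty cohort (no samples requested)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep(0L, n_control), rep(1L, n_albinism))
  tags <- c(
    if (n_control) rep_len(dataset_tags, n_control),
    if (n_albinism) rep_len(dataset_tags, n_albinism)
  )
  n <- length(labels)
  rows <- vector("list", n)
  geom <- patch_geometry()
  affine <- diag(4)
  affine[1:3, 4] <- -(geom$dims - 1) / 2
  for (i in seq_len(n)) {
    rendered <- NULL
    for (attempt in 0:49) {
      sub_seed <- .derive_seed(seed, i, attempt)
      params <- sample_phantom_params(labels[i], effect_config, sub_seed)
      rendered <- tryCatch(render_phantom(params, geom),
                           error = function(e) NULL)
      if (!is.null(rendered)) break
    }
    if (is.null(rendered)) {
      stop("generate_cohort: could not render sample ", i,
           " inside the patch after 50 jitter redraws", call. = FALSE)
    }
    noisy <- if (effect_config$noise_model == "gaussian") {
      .add_gaussian_noise(rendered$patch$voxels, params$noise_sigma,
                          .derive_seed(seed, i, 777))
    } else {
      add_rician_noise(rendered$patch$voxels, params$noise_sigma,
                       .derive_seed(seed, i, 777))
    }
    sid <- sprintf("s%04d", i)
    path <- file.path(out_dir, paste0(sid, ".nii.gz"))
    write_volume(volume(noisy, affine), path)
    write_volume(volume(rendered$mask + 0, affine), cohort_mask_path(path))
    truth <- unclass(params)
    jsonlite::write_json(truth, cohort_truth_path(path), auto_unbox = TRUE,
                         digits = NA)
    rows[[i]] <- data.frame(sample_id = sid, path = path,
                            label = labels[i], dataset_tag = tags[i],
                            cx = 0, cy = 0, cz = 0,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Sidecar paths of a cohort sample
#'
#' The ground-truth chiasm mask and parameter JSON written by
#' [generate_cohort()] live next to each patch, derived from its path.
#'
#' @param path Path of a sample's patch NIfTI.
#' @return The sidecar path.
#' @export
cohort_mask_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_mask.nii.gz", path)
}

#' @rdname cohort_mask_path
#' @export
cohort_truth_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_truth.json", path)
}

#' Reload ground-truth phantom parameters
#'
#' Reconstructs the `chiasm_phantom_params` object from the JSON sidecar
#' written by [generate_cohort()].
#'
#' @param path Truth JSON path (see [cohort_truth_path()]).
#' @return A `chiasm_phantom_params` list.
#' @export
read_phantom_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$jitter_translation_mm <- as.numeric(p$jitter_translation_mm)
  p$jitter_rotation_deg <- as.numeric(p$jitter_rotation_deg)
  structure(p, class = "chiasm_phantom_params")
}

#' Ground-truth vessel-distractor mask
#'
#' Renders the binary mask of the vessel capsule of a phantom (all zeros
#' when no vessel was drawn), under the same jitter as the main render.
#' Used to test that attribution maps are specific to the chiasm rather
#' than to vessel-like distractors.
#'
#' @param params A `chiasm_phantom_params`.
#' @param geometry Patch geometry.
#' @return Integer 0/1 array of patch shape.
#' @export
render_vessel_mask <- function(params, geometry = patch_geometry()) {
  d <- geometry$dims
  if (!isTRUE(params$vessel_present)) return(array(0L, dim = d))
  ax <- .patch_axis_coords()
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  v <- t(as.matrix(g))
  R <- .rotation_matrix(params$jitter_rotation_deg)
  u <- solve(R) %*% (v - params$jitter_translation_mm)
  corner <- list(c(8.5, 8.5), c(-8.5, 8.5), c(-8.5, -8.5),
                 c(8.5, -8.5))[[params$vessel_corner]]
  dv <- .capsule_distance(u, c(corner, -6), c(corner, 6), 1)
  wv <- .edge_weight(dv, params$edge_width_mm)
  array(as.integer(wv > 0.5), dim = d)
}

#' Embed a patch into a larger zero volume
#'
#' Places a patch into a zero-background volume (1 mm isotropic, identity
#' affine) so that [extract_patch()] at `center_world_mm` recovers it
#' exactly; a fixture generator for testing patch extraction.
#'
#' @param patch A [patch_volume()] or bare patch array.
#' @param volume_dims_mm Volume size in mm (= voxels at 1 mm).
#' @param center_world_mm Where the patch centre should land, world mm.
#' @return A [volume()].
#' @export
embed_patch_in_volume <- function(patch, volume_dims_mm = c(64, 64, 32),
                                  center_world_mm = volume_dims_mm / 2) {
  arr <- .patch_array(patch)
  pd <- dim(arr)
  vd <- as.integer(round(volume_dims_mm))
  c_vox <- .round_half_down(as.numeric(center_world_mm))
  start0 <- c_vox - pd %/% 2
  if (any(start0 < 0) || any(start0 + pd > vd)) {
    stop("embed_patch_in_volume: patch overflows the volume (start ",
         paste(start0, collapse = ","), ", volume ",
         paste(vd, collapse = "x"), ")", call. = FALSE)
  }
  vox <- array(0, dim = vd)
  vox[start0[1] + seq_len(pd[1]), start0[2] + seq_len(pd[2]),
      start0[3] + seq_len(pd[3])] <- arr
  volume(vox, diag(4))
}
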