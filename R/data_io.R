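# Patch extraction, intensity normalization, chiasm exclusion and manifest
# handling. Conventions (documented because the clinical pipeline leaves
# them open): world coordinates in RAS mm via the NIfTI affine; voxel
# indices 0-based; windows half-open; centres rounded to the nearest voxel
# with ties toward -Inf.

#' Extract the chiasm patch from a volume
#'
#' Returns the half-open 24 x 24 x 8 voxel window centred on the voxel
#' nearest to `center_world_mm`. Volumes whose affine is not 1 mm isotropic
#' axis-aligned are resampled on the fly with trilinear interpolation onto
#' the patch grid. Out-of-bounds voxels are zero-padded; more than 25%
#' padding raises a coverage error.
#'
#' @param vol A [volume()].
#' @param center_world_mm World coordinate (mm) of the chiasm centre.
#' @param geometry Patch geometry (fixed, see [patch_geometry()]).
#' @param sample_id Id attached to the returned patch.
#' @return A [patch_volume()].
#' @export
extract_patch <- function(vol, center_world_mm, geometry = patch_geometry(),
                          sample_id = "patch") {
  stopifnot(inherits(vol, "chiasm_volume"))
  d <- dim(vol$voxels)
  c_frac <- .world_to_voxel(vol$affine, center_world_mm)
  if (any(c_frac < -0.5) || any(c_frac > d - 0.5)) {
    stop("extract_patch: center is outside the volume", call. = FALSE)
  }
  pd <- geometry$dims
  direct <- .is_unit_grid(vol$affine)
  if (direct) {
    c_vox <- .round_half_down(c_frac)
    start0 <- c_vox - pd %/% 2
    out <- array(0, dim = pd)
    src_lo <- pmax(start0, 0)
    src_hi <- pmin(start0 + pd, d)
    if (all(src_hi > src_lo)) {
      dst <- Map(function(lo, hi, s) (lo - s + 1):(hi - s), src_lo, src_hi,
                 start0)
      src <- Map(function(lo, hi) (lo + 1):hi, src_lo, src_hi)
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        vol$voxels[src[[1]], src[[2]], src[[3]]]
    }
    n_inside <- prod(pmax(src_hi - src_lo, 0))
  } else {
    # resample: world positions of the patch grid centred on the nearest
    # voxel centre (mirroring the direct path's rounding)
    c_vox <- .round_half_down(c_frac)
    c_world <- (vol$affine %*% c(c_vox, 1))[1:3]
    ax <- .patch_axis_coords()
    g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    world <- t(as.matrix(g)) + c_world
    coords <- .world_to_voxel(vol$affine, world)
    out <- array(.trilinear(vol$voxels, coords, outside = 0), dim = pd)
    inside <- colSums(coords >= 0 & coords <= d - 1) == 3
    n_inside <- sum(inside)
  }
  pad_frac <- 1 - n_inside / prod(pd)
  if (pad_frac > 0.25) {
    stop(sprintf(
      "extract_patch: %.0f%% of the window lies outside the volume (max 25%%)",
      100 * pad_frac), call. = FALSE)
  }
  patch_volume(out, center_world_mm = as.numeric(center_world_mm),
               sample_id = sample_id)
}

# 1 mm isotropic, axis-aligned grids take the exact integer-window path;
# anything else goes through trilinear resampling.
.is_unit_grid <- function(affine, tol = 1e-6) {
  all(abs(affine[1:3, 1:3] - diag(3)) < tol)
}

#' Normalize patch intensities to [0,1]
#'
#' Robust min-max: intensities are clipped to the [1st, 99th] percentile
#' range and mapped linearly to [0,1]. Constant patches map to all zeros by
#' convention. Per-patch (not per-volume) so pre-extracted patch datasets
#' behave identically to on-the-fly extraction. Percentiles are inverse-ECDF
#' order statistics (quantile type 1): unlike interpolated quantiles they
#' commute exactly with the clipping, making the operation exactly
#' idempotent and exactly invariant to positive affine rescaling.
#'
#' @param patch A [patch_volume()] or bare array.
#' @param method Only `"robust_minmax"` is defined.
#' @return Same type as `patch`, values in [0,1].
#' @export
normalize_intensity <- function(patch, method = "robust_minmax") {
  method <- match.arg(method, "robust_minmax")
  x <- .patch_array(patch)
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE, type = 1)
  if (q[2] - q[1] <= 0) {
    return(.with_patch_array(patch, array(0, dim = dim(x))))
  }
  out <- (pmin(pmax(x, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  .with_patch_array(patch, array(out, dim = dim(x)))
}

#' Mask the chiasm out of a patch
#'
#' Replaces voxels under the mask by a fill value, producing the
#' chiasm-excluded inputs used for autoencoder pretraining (the feature
#' extractor must not see the structure the classifier is trained on).
#' `background_mean` (the default) fills with the mean of the unmasked
#' voxels; a zero fill would create an artificial landmark.
#'
#' @param patch A [patch_volume()] or bare array.
#' @param chiasm_mask Binary array, same shape as the patch.
#' @param fill `"background_mean"` or `"zero"`.
#' @return Same type as `patch` with masked voxels replaced.
#' @export
mask_chiasm_out <- function(patch, chiasm_mask,
                            fill = c("background_mean", "zero")) {
  fill <- match.arg(fill)
  x <- .patch_array(patch)
  if (!identical(dim(x), dim(chiasm_mask))) {
    stop("mask_chiasm_out: mask shape ",
         paste(dim(chiasm_mask), collapse = "x"),
         " does not match patch shape ", paste(dim(x), collapse = "x"),
         call. = FALSE)
  }
  m <- chiasm_mask > 0
  value <- if (fill == "zero") 0 else {
    if (all(m)) 0 else mean(x[!m])
  }
  x[m] <- value
  .with_patch_array(patch, x)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with header
#' `sample_id,path,label,dataset_tag,cx,cy,cz` (world-mm chiasm centre).
#' Loading validates uniqueness of ids, labels in {0,1} and path
#' resolvability, and reports every offending row.
#'
#' @param path CSV path.
#' @param check_paths Verify that each `path` exists (default TRUE).
#' @return A data.frame with one row per sample.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "path", "label", "dataset_tag",
                "cx", "cy", "cz")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("load_manifest: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    problems <- c(problems, paste0("duplicate sample_id in rows: ",
                                   paste(which(dup), collapse = ", ")))
  }
  bad_label <- !(df$label %in% c(0, 1))
  if (any(bad_label)) {
    problems <- c(problems, paste0("label not in {0,1} in rows: ",
                                   paste(which(bad_label), collapse = ", ")))
  }
  if (check_paths) {
    # paths may be stored relative to the manifest location
    resolved <- ifelse(file.exists(df$path), df$path,
                       file.path(dirname(path), df$path))
    bad_path <- !file.exists(resolved)
    if (any(bad_path)) {
      problems <- c(problems, paste0("unresolvable path in rows: ",
                                     paste(which(bad_path), collapse = ", ")))
    } else {
      df$path <- resolved
    }
  }
  if (length(problems)) {
    stop("load_manifest: invalid manifest:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df$label <- as.integer(df$label)
  for (col in c("cx", "cy", "cz")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname load_manifest
#' @param manifest Data.frame as returned by [generate_cohort()].
#' @export
save_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
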