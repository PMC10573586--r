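# Attribution (XAI) methods: saliency, gradient-x-input, occlusion,
# localization scoring against a ground-truth mask, and the class-average
# difference analysis. Signed maps are the canonical output; positive
# values push the score toward albinism.

.attribution_map <- function(values, method, sample_id = "patch") {
  stopifnot(is.array(values), all(is.finite(values)))
  structure(list(values = values, method = method, sample_id = sample_id),
            class = "attribution_map")
}

#' Saliency map
#'
#' Gradient of the albinism score with respect to each input voxel,
#' computed by exact reverse-mode differentiation of the network (no
#' finite-difference approximation). `signed = FALSE` returns magnitudes.
#'
#' @param model A `chiasm_classifier`.
#' @param patch A [patch_volume()] or patch array.
#' @param signed Keep the sign of the gradient (default TRUE).
#' @return An `attribution_map` (fields `values`, `method`, `sample_id`).
#' @export
saliency_map <- function(model, patch, signed = TRUE) {
  g <- .score_with_grad(model, patch)$grad
  if (!signed) g <- abs(g)
  sid <- if (inherits(patch, "chiasm_patch")) patch$sample_id else "patch"
  .attribution_map(g, "saliency", sid)
}

#' Gradient-times-input attribution
#'
#' Elementwise product of the signed saliency and the input; zero voxels
#' always receive zero attribution. For a linear model with zero baseline
#' the attributions sum to the score contribution of the input
#' (completeness), making this a cheap stand-in for reference-based
#' attribution methods.
#'
#' @inheritParams saliency_map
#' @return An `attribution_map`.
#' @export
gradient_x_input <- function(model, patch) {
  x <- .patch_array(patch)
  g <- .score_with_grad(model, patch)$grad
  sid <- if (inherits(patch, "chiasm_patch")) patch$sample_id else "patch"
  .attribution_map(g * x, "grad_x_input", sid)
}

#' Occlusion specification
#'
#' Defaults: a (4, 4, 2)-voxel window (about the chiasm-height scale) slid
#' with stride (2, 2, 1), filled with the patch's border-shell mean (a
#' mask-free background estimate); `"zero"` fill is available.
#'
#' @param window_voxels,stride_voxels 3-vectors, each `>= 1`.
#' @param fill `"background_mean"` or `"zero"`.
#' @return An `occlusion_spec` list.
#' @export
occlusion_spec <- function(window_voxels = c(4, 4, 2),
                           stride_voxels = c(2, 2, 1),
                           fill = c("background_mean", "zero")) {
  fill <- match.arg(fill)
  w <- as.integer(window_voxels); s <- as.integer(stride_voxels)
  stopifnot(length(w) == 3, length(s) == 3, all(w >= 1), all(s >= 1))
  if (any(w > patch_geometry()$dims)) {
    stop("occlusion_spec: window exceeds the patch dimensions",
         call. = FALSE)
  }
  structure(list(window_voxels = w, stride_voxels = s, fill = fill),
            class = "occlusion_spec")
}

#' Occlusion attribution map
#'
#' For every window placement on the stride grid, the score drop
#' `delta = score(patch) - score(occluded patch)` is recorded; each voxel's
#' attribution is the *mean* delta over all windows covering it (mean, not
#' sum, so maps are stride-invariant for additive models). Voxels covered
#' by no window get 0 with a warning. Occluded patches are scored in
#' batches.
#'
#' @param model A `chiasm_classifier`.
#' @param patch A [patch_volume()] or patch array.
#' @param spec An [occlusion_spec()].
#' @param batch_size Forward-pass batch size.
#' @return An `attribution_map`.
#' @export
occlusion_map <- function(model, patch, spec = occlusion_spec(),
                          batch_size = 64) {
  stopifnot(inherits(spec, "occlusion_spec"))
  x <- .patch_array(patch)
  d <- dim(x)
  w <- spec$window_voxels; s <- spec$stride_voxels
  if (any(w > d)) {
    stop("occlusion_map: window larger than the patch", call. = FALSE)
  }
  fill <- if (spec$fill == "zero") 0 else .border_mean(x)
  starts <- lapply(1:3, function(a) seq(1, d[a] - w[a] + 1, by = s[a]))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  base <- predict_score(model, x)

  n_win <- nrow(grid)
  deltas <- numeric(n_win)
  for (start in seq(1, n_win, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n_win)
    batch <- array(0, c(d, 1, length(idx)))
    for (j in seq_along(idx)) {
      g <- grid[idx[j], ]
      occ <- x
      occ[g$x:(g$x + w[1] - 1), g$y:(g$y + w[2] - 1),
          g$z:(g$z + w[3] - 1)] <- fill
      batch[, , , 1, j] <- occ
    }
    deltas[idx] <- base - predict_score(model, batch)
  }
  total <- array(0, d)
  cover <- array(0, d)
  for (i in seq_len(n_win)) {
    g <- grid[i, ]
    xs <- g$x:(g$x + w[1] - 1); ys <- g$y:(g$y + w[2] - 1)
    zs <- g$z:(g$z + w[3] - 1)
    total[xs, ys, zs] <- total[xs, ys, zs] + deltas[i]
    cover[xs, ys, zs] <- cover[xs, ys, zs] + 1
  }
  if (any(cover == 0)) {
    warning("occlusion_map: ", sum(cover == 0),
            " voxels covered by no window; their attribution is set to 0")
  }
  vals <- ifelse(cover > 0, total / pmax(cover, 1), 0)
  sid <- if (inherits(patch, "chiasm_patch")) patch$sample_id else "patch"
  .attribution_map(array(vals, d), "occlusion", sid)
}

#' Attribution localization score
#'
#' The fraction of the `floor(top_fraction * n)` voxels with the largest
#' absolute attribution that fall inside a reference mask — the package's
#' quantitative version of "the predictions are driven by the chiasm".
#' Ties at the cutoff are broken by voxel index order, so an all-equal map
#' scores deterministically (approximately the mask's volume fraction).
#'
#' @param map An `attribution_map` (or bare array).
#' @param mask Binary array of the same shape (e.g. the ground-truth
#'   chiasm mask).
#' @param top_fraction Fraction of voxels to rank, in (0, 1].
#' @return Fraction in [0, 1].
#' @export
localization_score <- function(map, mask, top_fraction = 0.05) {
  vals <- if (inherits(map, "attribution_map")) map$values else map
  stopifnot(identical(dim(vals), dim(mask)),
            top_fraction > 0, top_fraction <= 1)
  if (sum(mask > 0) == 0) {
    stop("localization_score: empty mask, score undefined", call. = FALSE)
  }
  n <- length(vals)
  m <- max(1L, as.integer(floor(top_fraction * n)))
  ord <- order(-abs(as.vector(vals)), seq_len(n)) # ties: voxel index order
  top <- ord[seq_len(m)]
  mean(mask[top] > 0)
}

#' Class-averaged patches and their difference maps
#'
#' Voxelwise mean patch per class and both signed differences; by
#' construction `diff_c_minus_a == -diff_a_minus_c` exactly. On this
#' package's phantoms the albinism-minus-control difference is positive at
#' the central crossing (the central intensity boost) and the
#' control-minus-albinism difference is positive over the lateral
#' chiasm/tract band (the wider control structure).
#'
#' @param patches List of patch arrays (same grid).
#' @param labels 0/1 vector, one per patch; both classes required.
#' @return List: `avg_control`, `avg_albinism`, `diff_c_minus_a`,
#'   `diff_a_minus_c`.
#' @export
class_average_and_difference <- function(patches, labels) {
  stopifnot(length(patches) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("class_average_and_difference: both classes must be present",
         call. = FALSE)
  }
  avg <- function(cls) {
    sel <- which(labels == cls)
    Reduce(`+`, lapply(patches[sel], .patch_array)) / length(sel)
  }
  a0 <- avg(0)
  a1 <- avg(1)
  list(avg_control = a0, avg_albinism = a1,
       diff_c_minus_a = a0 - a1, diff_a_minus_c = a1 - a0)
}

#' Binarize an average image below a threshold
#'
#' `mask = 1` where the value is below `threshold` — used to restrict
#' difference maps to the darker (non-white-matter) complement of each
#' class average before display or scoring.
#'
#' @param avg Patch-shaped numeric array (finite).
#' @param threshold Cut value.
#' @param direction Only `"below"` is defined.
#' @return Integer 0/1 array.
#' @export
threshold_mask <- function(avg, threshold, direction = "below") {
  direction <- match.arg(direction, "below")
  stopifnot(all(is.finite(avg)))
  array(as.integer(avg < threshold), dim = dim(avg))
}

#' Export an attribution map as NIfTI
#'
#' Written on the patch grid (1 mm isotropic, origin at the patch centre)
#' so it overlays its input patch in any NIfTI viewer.
#'
#' @param map An `attribution_map`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(map, path) {
  stopifnot(inherits(map, "attribution_map"))
  geom <- patch_geometry()
  affine <- diag(4)
  affine[1:3, 4] <- -(geom$dims - 1) / 2
  write_volume(volume(map$values, affine), path)
}
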