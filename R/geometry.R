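# Containers and spatial utilities shared across modules: the fixed patch
# grid, volumes with affines, world<->voxel mapping and trilinear sampling.

#' The fixed chiasm patch geometry
#'
#' The network operates on a fixed 24 x 24 x 8 mm patch at 1 mm isotropic
#' resolution (4608 voxels), large enough to contain the optic chiasm
#' (average width ~15 mm, height ~3.5 mm) even under the small rigid
#' training augmentations. Axes are RAS-ordered: left-right,
#' posterior-anterior, inferior-superior; the flat chiasm lies in the 8 mm
#' inferior-superior axis.
#'
#' @return A list with `size_mm`, `voxel_mm`, `dims` (voxels) and `axes`.
#' @export
patch_geometry <- function() {
  structure(list(
    size_mm = c(24, 24, 8),
    voxel_mm = c(1, 1, 1),
    dims = c(24L, 24L, 8L),
    axes = c("left-right", "posterior-anterior", "inferior-superior")
  ), class = "chiasm_patch_geometry")
}

#' Construct a volume (voxel array + affine)
#'
#' @param voxels 3-D numeric array.
#' @param affine 4x4 voxel-to-world (mm) matrix; must be invertible. Voxel
#'   indices entering the affine are 0-based.
#' @return A `chiasm_volume` list with elements `voxels` and `affine`.
#' @export
volume <- function(voxels, affine = diag(4)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) {
    stop("volume: affine is not invertible", call. = FALSE)
  }
  structure(list(voxels = voxels, affine = affine), class = "chiasm_volume")
}

#' Construct a patch volume
#'
#' A patch is the CNN's input unit: a 24 x 24 x 8 voxel array (1 mm
#' isotropic) with the world coordinate of its centre and a sample id.
#'
#' @param voxels Array with dimensions `patch_geometry()$dims`.
#' @param center_world_mm World (mm) coordinate of the patch centre.
#' @param sample_id Character id.
#' @return A `chiasm_patch` list: `voxels`, `center_world_mm`, `sample_id`.
#' @export
patch_volume <- function(voxels, center_world_mm = c(0, 0, 0),
                         sample_id = "patch") {
  geom <- patch_geometry()
  if (!is.array(voxels) || !identical(dim(voxels), geom$dims)) {
    stop("patch_volume: voxels must have dimensions ",
         paste(geom$dims, collapse = "x"), call. = FALSE)
  }
  if (!all(is.finite(voxels))) {
    stop("patch_volume: voxel values must be finite", call. = FALSE)
  }
  structure(list(voxels = voxels,
                 center_world_mm = as.numeric(center_world_mm),
                 sample_id = as.character(sample_id)),
            class = "chiasm_patch")
}

# Accept either a chiasm_patch or a bare array where only voxels are needed.
.patch_array <- function(patch) {
  if (inherits(patch, "chiasm_patch")) patch$voxels else patch
}

.with_patch_array <- function(patch, voxels) {
  if (inherits(patch, "chiasm_patch")) {
    patch$voxels <- voxels
    patch
  } else {
    voxels
  }
}

# World-mm coordinates of voxel centres of the canonical patch grid,
# centred on the origin: x in -11.5..11.5, y in -11.5..11.5, z in -3.5..3.5.
.patch_axis_coords <- function() {
  d <- patch_geometry()$dims
  lapply(d, function(n) seq_len(n) - 1 - (n - 1) / 2)
}

# Nearest-voxel rounding with ties toward -Inf (round-half-down).
.round_half_down <- function(x) ceiling(x - 0.5)

# Map world mm -> 0-based voxel coordinates.
.world_to_voxel <- function(affine, world) {
  inv <- solve(affine)
  w <- rbind(matrix(world, nrow = 3), 1)
  (inv %*% w)[1:3, , drop = TRUE]
}

# Rotation matrix from extrinsic x,y,z Euler angles in degrees.
.rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Vectorised trilinear interpolation of `arr` at 0-based fractional voxel
# coordinates `coords` (3 x n); values outside the grid default to `outside`.
.trilinear <- function(arr, coords, outside = 0) {
  d <- dim(arr)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(length(x))
  at <- function(i, j, k) {
    inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
      k >= 0 & k <= d[3] - 1
    v <- rep(outside, length(i))
    idx <- cbind(i[inside] + 1, j[inside] + 1, k[inside] + 1)
    if (nrow(idx)) v[inside] <- arr[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- at(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      val[nz] <- val[nz] + w[nz] * v
    }
  }
  val
}

# Rigidly shift a patch array by `shift_mm` (trilinear resampling, edge
# values fall back to `fill`). Used for training-time augmentation. A pure
# translation factorizes per axis, so the interpolation reduces to eight
# weighted integer-shifted slices — much cheaper than pointwise trilinear.
.shift_patch <- function(arr, shift_mm, fill = NULL) {
  d <- dim(arr)
  if (is.null(fill)) fill <- .border_mean(arr)
  src <- lapply(1:3, function(a) (0:(d[a] - 1)) - shift_mm[a])
  lo <- lapply(src, floor)
  fr <- Map(`-`, src, lo)
  out <- array(0, d)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    off <- list(dx, dy, dz)
    idx <- Map(function(l, o) l + o, lo, off)
    valid <- Map(function(i, a) i >= 0 & i <= d[a] - 1, idx, 1:3)
    safe <- Map(function(i, v) ifelse(v, i, 0L) + 1L, idx, valid)
    S <- arr[safe[[1]], safe[[2]], safe[[3]]]
    if (!all(valid[[1]])) S[!valid[[1]], , ] <- fill
    if (!all(valid[[2]])) S[, !valid[[2]], ] <- fill
    if (!all(valid[[3]])) S[, , !valid[[3]]] <- fill
    wx <- if (dx) fr[[1]] else 1 - fr[[1]]
    wy <- if (dy) fr[[2]] else 1 - fr[[2]]
    wz <- if (dz) fr[[3]] else 1 - fr[[3]]
    W <- outer(outer(wx, wy), wz)
    out <- out + W * S
  }
  out
}

# Mean intensity over the one-voxel border shell; a cheap, mask-free
# estimate of the background level of a patch.
.border_mean <- function(arr) {
  d <- dim(arr)
  inner <- arr[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  (sum(arr) - sum(inner)) / (length(arr) - length(inner))
}
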