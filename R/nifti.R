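# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package ships with this toolchain, so the subset of the format the
# package needs is implemented here: single-file .nii / .nii.gz, 3-D volumes,
# the common numeric datatypes, sform affine (qform ignored; pixdim fallback),
# scl_slope/scl_inter applied on read. Little- and big-endian files are read;
# files are always written little-endian float32 with an sform.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

.nifti_con <- function(path, mode) {
  # gzfile transparently handles both plain and gzip streams on read
  gzfile(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a [volume()]
#' (voxel array plus 4x4 voxel-to-world affine, RAS millimetres). Scaling
#' (`scl_slope`, `scl_inter`) is applied; the affine is taken from the sform
#' when `sform_code > 0`, otherwise a diagonal affine is built from `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `chiasm_volume` object; see [volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("read_volume: file not found: ", path, call. = FALSE)
  }
  con <- .nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE) {
    stop("read_volume: not a NIfTI-1 file (truncated header): ", path,
         call. = FALSE)
  }
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE) {
      stop("read_volume: not a NIfTI-1 file (bad sizeof_hdr): ", path,
           call. = FALSE)
    }
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("read_volume: not a NIfTI-1 file (bad magic '", magic, "'): ", path,
         call. = FALSE)
  }
  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4,
                                     endian = endian)
  dim_field <- rd_i16(40, 8)
  ndim <- dim_field[1]
  if (ndim < 1 || ndim > 7) {
    stop("read_volume: invalid dim[0] = ", ndim, call. = FALSE)
  }
  dims <- dim_field[2:(1 + max(ndim, 3))]
  dims[dims == 0] <- 1L
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  sform_code <- rd_i16(254, 1)
  srow <- matrix(rd_f32(280, 12), nrow = 3, byrow = TRUE)

  type <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1, signed = FALSE),
    "4"   = list(what = "integer", size = 2, signed = TRUE),
    "8"   = list(what = "integer", size = 4, signed = TRUE),
    "16"  = list(what = "double",  size = 4, signed = TRUE),
    "64"  = list(what = "double",  size = 8, signed = TRUE),
    "256" = list(what = "integer", size = 1, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    stop("read_volume: unsupported NIfTI datatype ", datatype, call. = FALSE)
  )
  n_vox <- prod(dims)
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = skip)
  vox <- readBin(con, type$what, n = n_vox, size = type$size,
                 signed = type$signed, endian = endian)
  if (length(vox) < n_vox) {
    stop("read_volume: truncated voxel data in ", path, call. = FALSE)
  }
  vox <- as.double(vox)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vox <- vox * scl_slope + scl_inter
  }
  arr <- array(vox, dim = dims)
  if (length(dims) > 3 && all(dims[-(1:3)] == 1L)) {
    arr <- array(vox, dim = dims[1:3])
  }
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    sp <- pixdim[2:4]
    sp[!is.finite(sp) | sp == 0] <- 1
    affine <- diag(c(sp, 1))
  }
  volume(arr, affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume()] as single-file NIfTI-1, float32, little-endian, with
#' the affine stored in the sform (code 2) and qform disabled. Paths ending
#' in `.gz` are gzip-compressed.
#'
#' @param vol A `chiasm_volume` (or a plain 3-D array, taken at 1 mm
#'   isotropic spacing with origin at voxel (0,0,0)).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (is.array(vol) && is.null(attr(vol, "affine")) && !inherits(vol, "chiasm_volume")) {
    vol <- volume(vol, diag(4))
  }
  stopifnot(inherits(vol, "chiasm_volume"))
  arr <- vol$voxels
  dims <- dim(arr)
  if (length(dims) != 3) {
    stop("write_volume: only 3-D volumes are supported", call. = FALSE)
  }
  sp <- sqrt(colSums(vol$affine[1:3, 1:3]^2))

  hdr <- raw(NIFTI_HDR_SIZE)
  put <- function(hdr, off, val, what, size) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, NIFTI_HDR_SIZE, "integer", 4)
  # dim[8]
  hdr <- put(hdr, 40, as.integer(c(3, dims, 1, 1, 1, 1)), "integer", 2)
  hdr <- put(hdr, 70, 16L, "integer", 2)                   # datatype float32
  hdr <- put(hdr, 72, 32L, "integer", 2)                   # bitpix
  hdr <- put(hdr, 76, c(1, sp, 1, 1, 1, 1), "double", 4)   # pixdim
  hdr <- put(hdr, 108, NIFTI_VOX_OFFSET, "double", 4)
  hdr <- put(hdr, 112, 1, "double", 4)                     # scl_slope
  hdr <- put(hdr, 116, 0, "double", 4)                     # scl_inter
  hdr <- put(hdr, 252, 0L, "integer", 2)                   # qform_code
  hdr <- put(hdr, 254, 2L, "integer", 2)                   # sform_code
  hdr <- put(hdr, 280, as.double(t(vol$affine[1:3, ])), "double", 4)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)                                    # extension flag
  writeBin(as.double(arr), con, size = 4, endian = "little")
  invisible(path)
}
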