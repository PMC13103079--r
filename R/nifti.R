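# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the target R stack, so the subset of the
# NIfTI-1 format this pipeline needs is implemented here directly: single-file
# .nii / .nii.gz, 3D grids, little- or big-endian input, float32/float64/
# int16/int32/uint8/uint16 storage, scl_slope/scl_inter scaling, and an
# sform voxel-to-world affine. Output is always little-endian .nii(.gz),
# float32 by default (int16 for label volumes), sform_code 1.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param provenance Provenance tag for the returned volume.
#' @return An [new_volume()] object; `scl_slope`/`scl_inter` are applied.
#' @export
read_nifti <- function(path, provenance = "bl") {
  if (!file.exists(path)) stop_lh("NIfTI file does not exist: '%s'", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop_lh("malformed NIfTI (truncated header): '%s'", path)
  rd <- function(off, what, n, size, endian, signed = TRUE) {
    rc <- rawConnection(hdr_raw[(off + 1):(off + n * size)])
    on.exit(close(rc))
    readBin(rc, what, n = n, size = size, endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, "big") != 348L)
      stop_lh("malformed NIfTI (bad sizeof_hdr): '%s'", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_lh("malformed NIfTI (bad magic '%s'): '%s'", magic, path)
  dims <- rd(40, "integer", 8, 2, endian)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[2:4] < 1L))
    stop_lh("unsupported NIfTI dimensionality (%d) in '%s'", ndim, path)
  if (ndim > 3L && any(dims[5:(ndim + 1)] > 1L))
    stop_lh("only 3D NIfTI volumes are supported: '%s'", path)
  dtcode <- rd(70, "integer", 1, 2, endian)
  dt <- NULL
  for (nm in names(NIFTI_DTYPES))
    if (NIFTI_DTYPES[[nm]]$code == dtcode) dt <- NIFTI_DTYPES[[nm]]
  if (is.null(dt)) stop_lh("unsupported NIfTI datatype code %d in '%s'", dtcode, path)
  pixdim <- rd(76, "double", 8, 4, endian)
  vox_offset <- rd(108, "double", 1, 4, endian)
  scl_slope <- rd(112, "double", 1, 4, endian)
  scl_inter <- rd(116, "double", 1, 4, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  srow <- rbind(rd(280, "double", 4, 4, endian),
                rd(296, "double", 4, 4, endian),
                rd(312, "double", 4, 4, endian))
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  n_vox <- as.double(nx) * ny * nz
  # Already consumed 348 bytes; skip to the data offset.
  skip <- max(0, round(vox_offset) - 348L)
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n_vox) stop_lh("malformed NIfTI (truncated data): '%s'", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  affine <- if (sform_code > 0L) srow else cbind(diag(spacing), c(0, 0, 0))
  new_volume(array(vals, dim = c(nx, ny, nz)), spacing = spacing,
             affine = affine, provenance = provenance)
}

#' Write a volume as NIfTI-1
#'
#' @param volume An [new_volume()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype Storage type: `"float32"` (default), `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, datatype = "float32") {
  if (!is_volume(volume)) stop_lh("write_nifti expects an lh_volume")
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt) || !datatype %in% c("float32", "int16", "uint8"))
    stop_lh("unsupported output datatype '%s'", datatype)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_lh("output directory does not exist: '%s'", dir)
  d <- dim(volume$data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                   # sizeof_hdr
  w(raw(34), 1)                                # data_type..session_error
  w(charToRaw("r"), 1); w(raw(1), 1)           # regular, dim_info
  w(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2)   # dim[8]
  w(numeric(3), 4)                             # intent_p1..p3
  w(0L, 2)                                     # intent_code
  w(dt$code, 2); w(dt$size * 8L, 2)            # datatype, bitpix
  w(0L, 2)                                     # slice_start
  w(c(1, volume$spacing, 1, 1, 1, 1), 4)       # pixdim (qfac first)
  w(352, 4)                                    # vox_offset
  w(1, 4); w(0, 4)                             # scl_slope, scl_inter
  w(0L, 2); w(raw(1), 1)                       # slice_end, slice_code
  w(as.raw(2L), 1)                             # xyzt_units: mm
  w(numeric(4), 4)                             # cal_max..toffset
  w(integer(2), 4)                             # glmax, glmin
  w(raw(104), 1)                               # descrip + aux_file
  w(0L, 2); w(1L, 2)                           # qform_code, sform_code
  w(numeric(6), 4)                             # quaternion + qoffset
  w(as.numeric(t(volume$affine)), 4)           # srow_x/y/z
  w(raw(16), 1)                                # intent_name
  w(c(charToRaw("n+1"), raw(1)), 1)            # magic
  w(raw(4), 1)                                 # extension indicator
  if (dt$what == "integer") w(as.integer(round(volume$data)), dt$size)
  else w(as.numeric(volume$data), dt$size)
  invisible(path)
}

#' Load a volume from disk
#'
#' Thin wrapper over [read_nifti()] matching the pipeline vocabulary.
#' @inheritParams read_nifti
#' @export
load_volume <- function(path, provenance = "bl") read_nifti(path, provenance)

#' Save a volume to disk
#'
#' @inheritParams write_nifti
#' @export
save_volume <- function(volume, path, datatype = "float32")
  write_nifti(volume, path, datatype)
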