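# Minimal single-file NIfTI-1 (.nii) reader/writer. The package stores the z
# axis as the first (fastest-varying) stored dimension, matching its global
# (z, y, x) convention; orientation metadata (qform/sform) is not interpreted
# -- the artifact is atlas-agnostic and consumes pre-aligned grids.

NIFTI_DT <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L, 512L),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  what = c("int", "int", "int", "double", "double", "int"),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
)

#' Write a 3D array as a NIfTI-1 file
#'
#' @param data 3D array `(z, y, x)`; stored with z as the first dimension.
#' @param path output `.nii` file.
#' @param spacing `(dz, dy, dx)` um, stored in `pixdim[1:3]`.
#' @param datatype `"auto"` (int32 for integer-valued data, float64
#'   otherwise), or one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing, datatype = "auto") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D (z, y, x) array")
  spacing <- check_spacing(spacing)
  if (identical(datatype, "auto"))
    datatype <- if (all(data == round(data)) && max(abs(data)) < 2^31) "int32"
                else "float64"
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stopf("unsupported datatype %s", datatype))
  row <- NIFTI_DT[NIFTI_DT$code == code, ]
  d <- dim(data)

  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w_chr <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  w_i32(348L)                                   # sizeof_hdr
  w_chr("", 10); w_chr("", 18)                  # data_type, db_name
  w_i32(0L); w_i16(0L); w_chr("r", 1); w_chr("", 1) # extents, session_error, regular, dim_info
  w_i16(c(3L, d[1], d[2], d[3], 1L, 1L, 1L, 1L))    # dim
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p1..3, intent_code
  w_i16(code); w_i16(row$size * 8L); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(c(1, spacing[1], spacing[2], spacing[3], 1, 1, 1, 1)) # pixdim
  w_f32(352); w_f32(1); w_f32(0)                # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_chr("", 1)                       # slice_end, slice_code
  writeBin(as.raw(2L), con)                     # xyzt_units: NIFTI_UNITS_MM stand-in
  w_f32(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_chr("lsmcount (z,y,x) volume", 80)          # descrip
  w_chr("", 24)                                 # aux_file
  w_i16(c(0L, 0L))                              # qform_code, sform_code
  w_f32(rep(0, 6))                              # quaternion + offsets
  w_f32(rep(0, 12))                             # srow_x/y/z
  w_chr("", 16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag = none

  v <- as.vector(data)
  if (row$what == "int") {
    v <- as.integer(round(v))
    if (code == 2L) { # uint8 via raw
      writeBin(as.raw(v), con)
    } else if (code == 4L) {
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(v, con, size = 4, endian = "little")
    }
  } else {
    writeBin(as.numeric(v), con, size = row$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file as a 3D array
#'
#' @param path `.nii` file (uncompressed, single-file).
#' @return list with `data` (3D array, first stored dimension = z) and
#'   `spacing` from `pixdim[1:3]`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 352L) stopf("not a NIfTI-1 file: %s", path)
  endian <- "little"
  hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
    if (hdr_size != 348L) stopf("not a NIfTI-1 file: %s", path)
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("bad NIfTI magic in %s", path)
  rd_i16 <- function(off, n) readBin(raw[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2, endian = endian)
  rd_f32 <- function(off, n) readBin(raw[(off + 1):(off + 4 * n)], "numeric",
                                     n = n, size = 4, endian = endian)
  dims <- rd_i16(40, 8)
  ndim <- dims[1]
  if (ndim < 3L) stopf("NIfTI image is not 3D: %s", path)
  if (ndim > 3L && any(dims[(5):(1 + ndim)] > 1L))
    stopf("NIfTI image has more than 3 non-singleton dimensions: %s", path)
  d <- dims[2:4]
  code <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  row <- NIFTI_DT[NIFTI_DT$code == code, ]
  if (!nrow(row)) stopf("unsupported NIfTI datatype code %d", code)
  n <- prod(d)
  off <- as.integer(vox_offset)
  bytes <- raw[(off + 1):(off + n * row$size)]
  v <- if (code == 2L) as.integer(readBin(bytes, "raw", n = n))
       else readBin(bytes, row$what, n = n, size = row$size, endian = endian,
                    signed = row$signed)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  list(data = array(v, d), spacing = as.numeric(pixdim[2:4]))
}
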