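# Minimal NIfTI-1 I/O.
#
# No NIfTI-capable R package is available in the target environment, so the
# package carries its own small codec for the single-file ".nii" flavour
# (optionally gzipped). Scope: 3D scalar volumes, the common datatypes, no
# extensions; scl_slope/scl_inter are honoured on read. qform/sform are
# written as a plain scaling matrix — the package assumes co-registered
# grids and never resamples, so orientation metadata is carried, not used.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, int8 = 256L, uint16 = 512L, uint32 = 768L)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a [vol3d].
#' Only 3D scalar images are supported; 4D images with a trailing singleton
#' dimension are accepted. Integer datatypes yield integer arrays (so label
#' volumes round-trip exactly) unless a non-trivial intensity scaling is
#' present.
#'
#' @param path file path.
#' @return a [vol3d].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- .Platform$endian
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1]
  if (ndim < 3L) stop("expected a 3D image, got ndim=", ndim, " in ", path)
  dims <- dim_field[2:(ndim + 1)]
  if (ndim > 3L && any(dims[4:ndim] != 1L))
    stop("only 3D scalar images supported; got dim ",
         paste(dims, collapse = "x"), " in ", path)
  dims <- dims[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  magic <- rawToChar(hdr_raw[345:348])
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("bad NIfTI magic in ", path)

  spec <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1L, signed = FALSE),
    "4"   = list(what = "integer", size = 2L, signed = TRUE),
    "8"   = list(what = "integer", size = 4L, signed = TRUE),
    "16"  = list(what = "numeric", size = 4L, signed = TRUE),
    "64"  = list(what = "numeric", size = 8L, signed = TRUE),
    "256" = list(what = "integer", size = 1L, signed = TRUE),
    "512" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported NIfTI datatype code ", datatype, " in ", path))

  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- as.numeric(vals) * scl_slope + scl_inter
  }
  vol3d(array(vals, dim = dims), voxel_size = abs(pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' Writes a [vol3d] as a single-file NIfTI-1 image. Integer arrays are
#' stored as int16 when they fit, otherwise int32; doubles as float32 by
#' default. Paths ending in `.gz` are gzip-compressed.
#'
#' @param x a [vol3d] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"auto"`, `"int16"`, `"int32"`, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = "auto") {
  if (length(dim(x)) != 3L) stop("write_nifti requires a 3D volume")
  vs <- voxel_size(x)
  vals <- as.vector(as_array3d(x))
  if (datatype == "auto") {
    datatype <- if (is.integer(vals) ||
                    (all(is.finite(vals)) && all(vals == round(vals)) &&
                     max(abs(vals)) <= .Machine$integer.max)) {
      if (max(abs(vals)) <= 32767) "int16" else "int32"
    } else "float32"
  }
  enc <- switch(datatype,
    int16   = list(code = NIFTI_DT$int16, size = 2L, int = TRUE,  bitpix = 16L),
    int32   = list(code = NIFTI_DT$int32, size = 4L, int = TRUE,  bitpix = 32L),
    float32 = list(code = NIFTI_DT$float32, size = 4L, int = FALSE, bitpix = 32L),
    float64 = list(code = NIFTI_DT$float64, size = 8L, int = FALSE, bitpix = 64L),
    stop("unsupported datatype: ", datatype))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L)
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L)
  w_i8  <- function(v) writeBin(as.integer(v), con, size = 1L)
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L)
  w_str <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r)))), con)
  }
  d <- dim(x)
  w_i32(348L)                    # sizeof_hdr       @0
  w_str("", 10L); w_str("", 18L) # data_type, db_name
  w_i32(0L); w_i16(0L); w_str("r", 1L); w_i8(0L)  # extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))                 # dim[8]           @40
  w_f32(c(0, 0, 0))                               # intent_p1..p3    @56
  w_i16(0L)                                       # intent_code      @68
  w_i16(enc$code); w_i16(enc$bitpix); w_i16(0L)   # datatype, bitpix, slice_start
  w_f32(c(1, vs, 1, 1, 1, 1))                     # pixdim[8]        @76
  w_f32(352)                                      # vox_offset       @108
  w_f32(1); w_f32(0)                              # scl_slope, scl_inter
  w_i16(0L); w_i8(0L); w_i8(2L)                   # slice_end, slice_code, xyzt_units=mm
  w_f32(c(0, 0))                                  # cal_max, cal_min @124
  w_f32(c(0, 0)); w_i32(c(0L, 0L))                # slice_duration, toffset, glmax, glmin
  w_str("nlfuse", 80L)                            # descrip          @148
  w_str("", 24L)                                  # aux_file         @228
  w_i16(1L); w_i16(1L)                            # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                      # quatern b,c,d, qoffset x,y,z
  w_f32(c(vs[1], 0, 0, 0))                        # srow_x           @280
  w_f32(c(0, vs[2], 0, 0))                        # srow_y
  w_f32(c(0, 0, vs[3], 0))                        # srow_z
  w_str("", 16L)                                  # intent_name      @328
  w_str("n+1", 4L)                                # magic (nul padded) @344
  writeBin(raw(4L), con)                          # extension flag
  if (enc$int) writeBin(as.integer(round(vals)), con, size = enc$size)
  else writeBin(as.numeric(vals), con, size = enc$size)
  invisible(path)
}
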