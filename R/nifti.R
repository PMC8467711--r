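# Minimal NIfTI-1 input/output ------------------------------------------------
#
# Uncompressed single-file .nii, written as float64 with scl_slope = 1 so
# that write -> read round trips are bit exact.  Reading supports the common
# integer and float datatypes with scl_slope/scl_inter applied.  Orientation
# metadata beyond pixdim is not interpreted: the package works in voxel
# coordinates (coregistration/resampling is out of scope).

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

#' Write a numeric array as an uncompressed NIfTI-1 volume
#'
#' @param x Numeric or logical array of 1 to 5 dimensions.
#' @param path Output file name (conventionally `.nii`).
#' @param voxel_size_mm Numeric voxel edge lengths for the spatial dims.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  x[] <- as.double(x)
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) > 5L) stop("at most 5 dimensions supported")
  dim8 <- c(length(d), d, rep(1L, 7L - length(d)))
  pixdim <- c(1, voxel_size_mm[seq_len(min(3L, length(d)))],
              rep(1, 7L - min(3L, length(d))))
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(v, size = 4L) writeBin(as.integer(v), con, size = size,
                                        endian = "little")
  wF <- function(v, size = 4L) writeBin(as.double(v), con, size = size,
                                        endian = "little")
  wC <- function(s, width) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), width))],
               raw(width - min(length(raw), width))), con)
  }
  wI(348L)                      # sizeof_hdr
  wC("", 10L); wC("", 18L)      # data_type, db_name (unused)
  wI(0L); wI(0L, 2L)            # extents, session_error
  wC("r", 1L); wC("", 1L)       # regular, dim_info
  wI(dim8, 2L)                  # dim[8]
  wF(c(0, 0, 0))                # intent_p1..p3
  wI(0L, 2L)                    # intent_code
  wI(64L, 2L); wI(64L, 2L)      # datatype float64, bitpix
  wI(0L, 2L)                    # slice_start
  wF(pixdim)                    # pixdim[8]
  wF(352)                       # vox_offset
  wF(1); wF(0)                  # scl_slope, scl_inter
  wI(0L, 2L); wC("", 1L); wC("", 1L)   # slice_end, slice_code, xyzt_units
  wF(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L))                 # glmax, glmin
  wC("condtensor", 80L)         # descrip
  wC("", 24L)                   # aux_file
  wI(c(0L, 0L), 2L)             # qform_code, sform_code
  wF(rep(0, 6))                 # quatern b,c,d, qoffset x,y,z
  wF(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0))  # srow_x/y/z
  wC("", 16L); wC("n+1", 4L)    # intent_name, magic
  writeBin(raw(4L), con)        # extension flag
  writeBin(as.vector(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' @param path File name of a `.nii` volume.
#' @return Numeric array with attribute `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    if (bitwAnd(sz, 0xFFL) == 0x5CL || sz != 348L) {
      seek(con, 0L)
      sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      if (sz != 348L) stop("not a NIfTI-1 file: ", path)
    }
  }
  seek(con, 40L)
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dim8[1L]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI dim field in ", path)
  d <- dim8[1L + seq_len(ndim)]
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl <- readBin(con, "double", 2L, size = 4L, endian = endian)
  seek(con, as.integer(vox_offset))
  n <- prod(d)
  x <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
               endian = endian)
  x <- as.double(x)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    x <- x * scl[1] + scl[2]
  dim(x) <- d
  attr(x, "voxel_size_mm") <- pixdim[2L:(1L + min(3L, ndim))]
  x
}

# bval / bvec text files ------------------------------------------------------
# Dialect: bvals are one whitespace-separated line; bvecs are three lines
# (x, y, z components), one column per acquisition.  Directions are given in
# the image coordinate frame.

#' Write b-values and gradient directions as text files
#'
#' @param b_values Numeric vector of b-values (s/mm^2), one per acquisition.
#' @param directions Numeric matrix `n x 3` of gradient directions.
#' @param bval_path,bvec_path Output file names.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_bvals_bvecs <- function(b_values, directions, bval_path, bvec_path) {
  stopifnot(length(b_values) == nrow(directions), ncol(directions) == 3L)
  writeLines(paste(format(b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(directions), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read b-values and gradient directions from text files
#'
#' @param bval_path,bvec_path File names in the one-line / three-line
#'   whitespace-separated dialect of [write_bvals_bvecs()].
#' @return List with `b_values` (numeric vector) and `directions`
#'   (`n x 3` matrix).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  v <- scan(bvec_path, quiet = TRUE)
  if (length(v) != 3L * length(b))
    stop("bvec entry count does not match bval count")
  directions <- t(matrix(v, nrow = 3L, byrow = TRUE))
  list(b_values = b, directions = directions)
}
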