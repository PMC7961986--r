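# Minimal single-file NIfTI-1 reader/writer.
#
# Supports .nii and .nii.gz, 3D/4D volumes, the numeric datatypes produced
# by common scanners and analysis tools (uint8, int16, int32, float32,
# float64), scl_slope/scl_inter scaling, and both endiannesses on read.
# Output is always float32 (maps) unless `datatype = "float64"`. Orientation
# is carried through verbatim as the srow matrix; no resampling ever occurs.

.NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                  `4` = list(what = "integer", size = 2, signed = TRUE),
                  `8` = list(what = "integer", size = 4, signed = TRUE),
                  `16` = list(what = "double", size = 4, signed = TRUE),
                  `64` = list(what = "double", size = 8, signed = TRUE))

.nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a `volume_image`: the data array (3D or 4D) with attributes
#'   `spacing` (voxel size, mm, per spatial axis), `srow` (3x4 orientation
#'   rows) and `path`.
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  con <- .nii_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  assert_that(length(hdr_raw) == 348, "malformed NIfTI file (%s): short header",
              path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    assert_that(sizeof_hdr == 348L, "malformed NIfTI file (%s): bad header size",
                path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  assert_that(magic %in% c("n+1", "ni1"), "malformed NIfTI file (%s): magic '%s'",
              path, magic)
  dim0 <- readBin(hdr_raw[41:56], "integer", 8, 2, endian = endian)
  ndim <- dim0[1]
  assert_that(ndim >= 3 && ndim <= 4, "unsupported NIfTI dimensionality %d (%s)",
              ndim, path)
  dims <- dim0[2:(1 + ndim)]
  datatype <- readBin(hdr_raw[71:72], "integer", 1, 2, endian = endian)
  dt <- .NIFTI_DT[[as.character(datatype)]]
  assert_that(!is.null(dt), "unsupported NIfTI datatype %d (%s)", datatype,
              path)
  pixdim <- readBin(hdr_raw[77:108], "double", 8, 4, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", 1, 4, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", 1, 4, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", 1, 4, endian = endian)
  srow <- matrix(readBin(hdr_raw[281:328], "double", 12, 4, endian = endian),
                 nrow = 3, byrow = TRUE)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  assert_that(length(vals) == n, "malformed NIfTI file (%s): truncated data",
              path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  structure(array(as.numeric(vals), dim = dims),
            spacing = pixdim[2:4], srow = srow, path = path,
            class = "volume_image")
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array (a `volume_image` keeps its spacing
#'   and orientation; plain arrays get the supplied `spacing` and an
#'   axis-aligned orientation).
#' @param path output `.nii` or `.nii.gz`.
#' @param spacing voxel size (mm) per spatial axis.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = NULL,
                         datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  assert_that(!is.null(dims) && length(dims) %in% c(3, 4),
              "data must be a 3D or 4D array")
  spacing <- spacing %||% attr(data, "spacing") %||% c(1, 1, 1)
  srow <- attr(data, "srow") %||%
    cbind(diag(spacing, 3), c(0, 0, 0))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)

  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L
  ndim <- length(dims)
  dim8 <- as.integer(c(ndim, dims, rep(1, 7 - ndim)))
  pixdim8 <- c(1, spacing, rep(1, 4))

  con <- .nii_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4)                               # sizeof_hdr
  writeBin(raw(35), con)                               # unused
  writeBin(as.raw(0), con)                             # dim_info
  writeBin(dim8, con, 2)                               # dim
  writeBin(numeric(3), con, 4)                         # intent_p1..p3
  writeBin(0L, con, 2)                                 # intent_code
  writeBin(code, con, 2)                               # datatype
  writeBin(8L * size, con, 2)                          # bitpix
  writeBin(0L, con, 2)                                 # slice_start
  writeBin(pixdim8, con, 4)                            # pixdim
  writeBin(352, con, 4)                                # vox_offset
  writeBin(1, con, 4)                                  # scl_slope
  writeBin(0, con, 4)                                  # scl_inter
  writeBin(0L, con, 2)                                 # slice_end
  writeBin(as.raw(c(0, 0)), con)                       # slice_code, xyzt_units
  writeBin(numeric(3), con, 4)                         # cal_max/min, slice_dur
  writeBin(0, con, 4)                                  # toffset
  writeBin(c(0L, 0L), con, 4)                          # glmax, glmin
  writeBin(raw(104), con)                              # descrip + aux_file
  writeBin(c(0L, 1L), con, 2)                          # qform, sform codes
  writeBin(numeric(6), con, 4)                         # quatern b,c,d + offsets
  writeBin(as.numeric(t(srow)), con, 4)                # srow_x/y/z
  writeBin(raw(16), con)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)        # magic
  writeBin(raw(4), con)                                # extension flag
  writeBin(as.numeric(data), con, size)
  invisible(path)
}

#' Read a binary mask volume
#'
#' A mask must contain only the values 0 and 1 (any supported datatype).
#'
#' @param path NIfTI file.
#' @return logical 3D array with spacing/orientation attributes.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  assert_that(all(v %in% c(0, 1)), "mask %s contains values other than 0/1",
              path)
  m <- array(v == 1, dim = dim(v))
  attributes(m)$spacing <- attr(v, "spacing")
  m
}
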