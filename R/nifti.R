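# Minimal NIfTI-1 I/O (.nii / .nii.gz, little-endian).  No NIfTI
# package is available in this stack, so the 348-byte header is read and
# written directly.  Supports 3D and channel-last 4D volumes, float32 /
# uint8 / int16 / int32 / float64 on read, float32 (images) and uint8
# (labels) on write, spacing via pixdim and the affine via the sform
# rows.

nifti_open <- function(path, mode) {
  con <- gzfile(path, mode)  # transparently handles plain .nii too
  con
}

read_nifti_header <- function(con) {
  raw_hdr <- readBin(con, "raw", 348)
  if (length(raw_hdr) < 348) stop("nifti: truncated header")
  rd <- function(what, n, size, offset, endian = "little")
    readBin(raw_hdr[(offset + 1):348], what, n = n, size = size,
            endian = endian)
  sz <- rd("integer", 1, 4, 0)
  endian <- "little"
  if (sz != 348) {
    endian <- "big"
    sz <- rd("integer", 1, 4, 0, endian)
    if (sz != 348) stop("nifti: not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  dim <- rd("integer", 8, 2, 40, endian)
  datatype <- rd("integer", 1, 2, 70, endian)
  bitpix <- rd("integer", 1, 2, 72, endian)
  pixdim <- rd("numeric", 8, 4, 76, endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian)
  srow <- matrix(rd("numeric", 12, 4, 280, endian), 3, 4, byrow = TRUE)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("nifti: bad magic '", magic, "'")
  list(dim = dim, datatype = datatype, bitpix = bitpix, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope,
       scl_inter = scl_inter, srow = srow, endian = endian)
}

read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  ndim <- h$dim[1]
  if (!ndim %in% c(3L, 4L)) stop("nifti: only 3D/4D volumes supported")
  shape <- h$dim[2:(1 + ndim)]
  n <- prod(shape)
  # skip up to vox_offset (348 already read)
  skip <- round(h$vox_offset) - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(h$datatype),
    "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE,
                             endian = h$endian)),
    "4" = as.numeric(readBin(con, "integer", n, 2, endian = h$endian)),
    "8" = as.numeric(readBin(con, "integer", n, 4, endian = h$endian)),
    "16" = readBin(con, "numeric", n, 4, endian = h$endian),
    "64" = readBin(con, "numeric", n, 8, endian = h$endian),
    stop("nifti: unsupported datatype ", h$datatype))
  if (length(vals) < n) stop("nifti: truncated data section")
  slope <- h$scl_slope
  if (is.finite(slope) && slope != 0 && !(slope == 1 && h$scl_inter == 0))
    vals <- vals * slope + h$scl_inter
  list(data = array(vals, shape), spacing = h$pixdim[2:4],
       srow = h$srow)
}

write_nifti <- function(data, path, spacing, srow = NULL,
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  dm <- dim(data)
  ndim <- length(dm)
  if (!ndim %in% c(3, 4)) stop("nifti: only 3D/4D volumes supported")
  if (is.null(srow)) {
    srow <- cbind(diag(as.numeric(spacing)), c(0, 0, 0))
  }
  dcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                  # sizeof_hdr
  w(raw(36), 1)                               # data_type..dim_info
  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(1 + ndim)] <- dm
  if (ndim == 3) dims[5] <- 1L
  dims[dims == 0] <- 1L
  w(as.integer(dims), 2)                      # dim
  w(numeric(3), 4)                            # intent_p1..3
  w(0L, 2)                                    # intent_code
  w(dcode, 2)                                 # datatype
  w(bitpix, 2)                                # bitpix
  w(0L, 2)                                    # slice_start
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- as.numeric(spacing)
  pixdim[5] <- 1
  w(pixdim, 4)                                # pixdim
  w(352, 4)                                   # vox_offset
  w(c(1, 0), 4)                               # scl_slope, scl_inter
  w(0L, 2); w(raw(2), 1)                      # slice_end, slice_code/units
  w(numeric(4), 4)                            # cal_max..toffset
  w(c(0L, 0L), 4)                             # glmax, glmin
  w(raw(104), 1)                              # descrip + aux_file
  w(c(0L, 1L), 2)                             # qform_code, sform_code
  w(numeric(6), 4)                            # quatern/qoffset
  w(as.numeric(t(srow)), 4)                   # srow_x/y/z
  w(raw(16), 1)                               # intent_name
  writeBin(charToRaw("n+1"), con)
  w(raw(1), 1)                                # magic NUL
  w(raw(4), 1)                                # extension flag
  if (datatype == "float32") {
    w(as.numeric(data), 4)
  } else {
    if (any(data < 0) || any(data > 255)) stop("nifti: uint8 overflow")
    writeBin(as.raw(as.integer(round(data))), con)
  }
  invisible(path)
}

#' Read a multi-channel Dixon volume from NIfTI
#'
#' Accepts either one 4D channel-last file (channel order water, fat,
#' fat_fraction) or three 3D files.  Spacing is read from the header and
#' must agree across channels.
#'
#' @param path path to a 4D file, or character vector / list of three 3D
#'   paths in order water, fat, fat_fraction.
#' @return a \code{\link{seg_volume}} (the header affine is attached as
#'   attribute \code{"srow"}).
#' @export
read_volume <- function(path) {
  if (length(path) == 1) {
    r <- read_nifti(path[[1]])
    if (length(dim(r$data)) != 4 || dim(r$data)[4] != 3)
      stop("read_volume: single file must be 4D with 3 channels")
    v <- seg_volume(r$data[, , , 1], r$data[, , , 2],
                    pmin(pmax(r$data[, , , 3], 0), 1), r$spacing)
    attr(v, "srow") <- r$srow
    return(v)
  }
  if (length(path) != 3)
    stop("read_volume: need one 4D file or three 3D files")
  rs <- lapply(path, read_nifti)
  shp <- dim(rs[[1]]$data)
  for (i in 2:3) {
    if (!identical(dim(rs[[i]]$data), shp))
      stop("read_volume: channel shape mismatch between files")
    if (max(abs(rs[[i]]$spacing - rs[[1]]$spacing)) > 1e-4)
      stop("read_volume: channel spacing mismatch between files")
  }
  v <- seg_volume(rs[[1]]$data, rs[[2]]$data,
                  pmin(pmax(rs[[3]]$data, 0), 1), rs[[1]]$spacing)
  attr(v, "srow") <- rs[[1]]$srow
  v
}

#' Write a multi-channel Dixon volume as 4D NIfTI
#'
#' @param v a \code{\link{seg_volume}}.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(v, path) {
  dm <- dim(v$channels$water)
  data <- array(0, c(dm, 3))
  data[, , , 1] <- v$channels$water
  data[, , , 2] <- v$channels$fat
  data[, , , 3] <- v$channels$fat_fraction
  write_nifti(data, path, v$spacing, srow = attr(v, "srow"),
              datatype = "float32")
}

#' Read / write label grids as NIfTI
#'
#' Labels round-trip losslessly (written as uint8).
#'
#' @param path NIfTI path.
#' @export
read_labels <- function(path) {
  r <- read_nifti(path)
  if (length(dim(r$data)) != 3) stop("read_labels: labels must be 3D")
  lv <- label_volume(array(as.integer(round(r$data)), dim(r$data)),
                     r$spacing)
  attr(lv, "srow") <- r$srow
  lv
}

#' @rdname read_labels
#' @param lv a \code{\link{label_volume}}.
#' @export
write_labels <- function(lv, path) {
  write_nifti(lv$labels, path, lv$spacing, srow = attr(lv, "srow"),
              datatype = "uint8")
}
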