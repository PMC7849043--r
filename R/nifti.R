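# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer. Only what this
# package needs: single-file NIfTI-1 ("n+1"), little- or big-endian,
# datatypes uint8/int8/int16/uint16/int32/float32/float64, scl_slope/inter
# applied on read. Volumes are written as float64, labels as int32, and
# displacement fields as 5-D (nx, ny, nz, 1, 3) with the displacement
#-vector intent code, one sub-volume per component (fastest-varying last).
# Spatial metadata is limited to voxel spacing (pixdim); affine/qform
# handling is out of scope.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352L

niftiDatatype <- function(code) {
  switch(as.character(code),
    "2" = list(what = "integer", size = 1L, signed = FALSE),
    "4" = list(what = "integer", size = 2L, signed = TRUE),
    "8" = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double", size = 4L, signed = TRUE),
    "64" = list(what = "double", size = 8L, signed = TRUE),
    "256" = list(what = "integer", size = 1L, signed = TRUE),
    "512" = list(what = "integer", size = 2L, signed = FALSE),
    stop("malformed or unsupported NIfTI datatype code: ", code))
}

isGzFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

readAllBytes <- function(path) {
  if (isGzFile(path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", 2^22)
      if (length(b) == 0L) break
      chunks[[length(chunks) + 1L]] <- b
    }
    do.call(c, chunks)
  } else {
    readBin(path, "raw", file.info(path)$size)
  }
}

parseNiftiHeader <- function(bytes, path) {
  if (length(bytes) < NIFTI_HDR_SIZE)
    stop("malformed NIfTI header in ", path, ": file too short")
  rd <- function(offset, what, n, size, endian) {
    con <- rawConnection(bytes[(offset + 1L):(offset + n * size)])
    on.exit(close(con))
    readBin(con, what, n = n, size = size, endian = endian,
            signed = !(size == 1L && what == "integer"))
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != NIFTI_HDR_SIZE)
      stop("malformed NIfTI header in ", path, ": bad sizeof_hdr")
  }
  magic <- rawToChar(bytes[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI header in ", path, ": bad magic")
  dims <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L)
    stop("malformed NIfTI header in ", path, ": dim[0] = ", ndim)
  list(endian = endian,
       dim = dims[2:(1 + ndim)],
       datatype = rd(70L, "integer", 1L, 2L, endian),
       pixdim = rd(76L, "double", 8L, 4L, endian),
       voxOffset = rd(108L, "double", 1L, 4L, endian),
       sclSlope = rd(112L, "double", 1L, 4L, endian),
       sclInter = rd(116L, "double", 1L, 4L, endian))
}

readNiftiRaw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readAllBytes(path)
  hdr <- parseNiftiHeader(bytes, path)
  dt <- niftiDatatype(hdr$datatype)
  n <- prod(hdr$dim)
  off <- max(as.integer(round(hdr$voxOffset)), NIFTI_HDR_SIZE)
  if (length(bytes) < off + n * dt$size)
    stop("malformed NIfTI file ", path, ": truncated data section")
  con <- rawConnection(bytes[(off + 1L):(off + n * dt$size)])
  on.exit(close(con))
  data <- readBin(con, dt$what, n = n, size = dt$size, endian = hdr$endian,
                  signed = dt$signed)
  data <- as.double(data)
  if (is.finite(hdr$sclSlope) && hdr$sclSlope != 0 &&
      !(hdr$sclSlope == 1 && hdr$sclInter == 0))
    data <- data * hdr$sclSlope + hdr$sclInter
  list(data = data, dim = hdr$dim, pixdim = hdr$pixdim)
}

writeNiftiRaw <- function(data, dims, path, spacing, datatype,
                          intentCode = 0L) {
  dt <- niftiDatatype(datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  ndim <- length(dims)
  dimField <- integer(8)
  dimField[1] <- ndim
  dimField[2:(1 + ndim)] <- as.integer(dims)
  if (ndim < 7L) dimField[(2 + ndim):8] <- 1L
  pixdim <- rep(1, 8)
  pixdim[2:4] <- spacing
  wb(NIFTI_HDR_SIZE, 4L)                       # sizeof_hdr
  wb(raw(36L), 1L)                             # unused through dim_info
  wb(dimField, 2L)                             # dim
  wb(rep(0, 3), 4L)                            # intent_p1..p3
  wb(as.integer(intentCode), 2L)               # intent_code
  wb(as.integer(datatype), 2L)                 # datatype
  wb(as.integer(dt$size * 8L), 2L)             # bitpix
  wb(0L, 2L)                                   # slice_start
  wb(pixdim, 4L)                               # pixdim
  wb(as.numeric(NIFTI_VOX_OFFSET), 4L)         # vox_offset (float)
  wb(1, 4L)                                    # scl_slope
  wb(0, 4L)                                    # scl_inter
  wb(0L, 2L)                                   # slice_end
  wb(raw(2L), 1L)                              # slice_code, xyzt_units
  wb(rep(0, 4), 4L)                            # cal_max..toffset
  wb(c(0L, 0L), 4L)                            # glmax, glmin
  desc <- charToRaw("gcdeform")
  wb(c(desc, raw(80L - length(desc))), 1L)     # descrip
  wb(raw(24L), 1L)                             # aux_file
  wb(c(0L, 0L), 2L)                            # qform_code, sform_code
  wb(rep(0, 6), 4L)                            # quatern/qoffset
  srow <- rbind(c(spacing[1], 0, 0, 0), c(0, spacing[2], 0, 0),
                c(0, 0, spacing[3], 0))
  wb(as.numeric(t(srow)), 4L)                  # srow_x/y/z
  wb(raw(16L), 1L)                             # intent_name
  wb(c(charToRaw("n+1"), raw(1L)), 1L)         # magic
  wb(raw(4L), 1L)                              # extender
  if (dt$what == "integer") wb(as.integer(data), dt$size)
  else wb(as.numeric(data), dt$size)
  invisible(path)
}

#' Read a scalar volume from a NIfTI-1 file
#'
#' Accepts plain or gzipped single-file NIfTI-1 with 3 spatial dimensions
#' (trailing singleton dimensions are dropped). Spacing is taken from
#' pixdim. Non-finite intensities are rejected.
#'
#' @param path file path (.nii or .nii.gz).
#' @return a [Volume].
#' @export
readVolume <- function(path) {
  r <- readNiftiRaw(path)
  d <- r$dim
  keep <- d
  while (length(keep) > 3L && keep[length(keep)] == 1L)
    keep <- keep[-length(keep)]
  if (length(keep) != 3L)
    stop("wrong dimensionality for a scalar volume: ", path, " has dims ",
         paste(d, collapse = "x"))
  if (any(!is.finite(r$data)))
    stop("volume contains non-finite intensities: ", path)
  Volume(array(r$data, keep), pmax(r$pixdim[2:4], .Machine$double.eps))
}

#' Read an integer label volume from a NIfTI-1 file
#'
#' @param path file path; voxel values must be non-negative integers.
#' @return a [LabelVolume].
#' @export
readLabels <- function(path) {
  v <- readVolume(path)
  if (any(v@data != round(v@data)))
    stop("non-integer labels in ", path,
         ": a label volume must hold integer region ids")
  LabelVolume(v@data, v@spacing)
}

#' Read a displacement field from a NIfTI-1 file
#'
#' Accepts a 4-D (nx, ny, nz, 3) or 5-D (nx, ny, nz, 1, 3) layout with the
#' vector components in the trailing dimension, in voxel units.
#'
#' @param path file path.
#' @return a [DisplacementField].
#' @export
readField <- function(path) {
  r <- readNiftiRaw(path)
  d <- r$dim
  if (length(d) == 5L && d[4] == 1L && d[5] == 3L) d <- d[c(1:3, 5L)]
  if (length(d) != 4L || d[4] != 3L)
    stop("wrong dimensionality for a displacement field: ", path,
         " has dims ", paste(r$dim, collapse = "x"),
         " (need trailing vector dimension of size 3)")
  DisplacementField(array(r$data, d),
                    pmax(r$pixdim[2:4], .Machine$double.eps))
}

#' Write a volume, label volume, or displacement field as NIfTI-1
#'
#' Volumes are stored as float64, labels as int32, fields as 5-D
#' (nx, ny, nz, 1, 3) float64 with the displacement-vector intent code.
#' A ".gz" suffix triggers gzip compression.
#'
#' @param x a [Volume], [LabelVolume] or [DisplacementField].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeNifti <- function(x, path) {
  if (is(x, "LabelVolume")) {
    writeNiftiRaw(x@data, dim(x@data), path, x@spacing, 8L)
  } else if (is(x, "DisplacementField")) {
    d <- dim(x@vectors)
    writeNiftiRaw(x@vectors, c(d[1:3], 1L, 3L), path, x@spacing, 64L,
                  intentCode = 1006L)
  } else if (is(x, "Volume")) {
    writeNiftiRaw(x@data, dim(x@data), path, x@spacing, 64L)
  } else stop("cannot write objects of class ", class(x), " as NIfTI")
  invisible(path)
}
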