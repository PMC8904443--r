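# Minimal NIfTI-1 single-file (.nii, uncompressed) reader/writer.
# Supports uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64),
# up to 5 dimensions, little- or big-endian on read, little-endian on
# write, no extensions. Enough for the package's interchange dialect:
# paired real/imaginary (or magnitude-only) volumes plus byte masks.

nifti_dtypes <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE))

#' Write an array as a NIfTI-1 volume
#'
#' @param data numeric/integer array, up to 5 dimensions.
#' @param path output path ending in `.nii`.
#' @param pixdim grid spacings for each dimension (mm for space, s for
#'   time), recycled/padded to the array's dimensionality.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64, default).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = 1, datatype = 64L) {
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) > 5L) stop("at most 5 dimensions supported", call. = FALSE)
  dim8 <- integer(8); dim8[1] <- length(d); dim8[2:(1 + length(d))] <- d
  dim8[dim8 == 0L] <- 1L
  pd8 <- numeric(8); pd8[1] <- 1
  pd8[2:(1 + length(d))] <- rep_len(pixdim, length(d))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused + dim_info
  writeBin(as.integer(dim8), con, size = 2, endian = "little")   # dim[8]
  writeBin(raw(14), con)                # intent_p1..p3, intent_code
  writeBin(as.integer(datatype), con, size = 2, endian = "little")
  writeBin(as.integer(dt$size * 8L), con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(pd8, con, size = 4, endian = "little")           # pixdim[8]
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope/inter
  writeBin(raw(224), con)               # slice_end .. intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)             # magic
  writeBin(as.raw(c(0, 0, 0, 0, 0)), con)   # magic NUL + extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else writeBin(as.double(vals), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a single-file, uncompressed `.nii`.
#' @return List with \code{data} (array), \code{dim}, \code{pixdim}
#'   (per-dimension spacings), \code{datatype}.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 352)
    stop("corrupted NIfTI header: file shorter than 352 bytes", call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L)
      stop("corrupted NIfTI header: sizeof_hdr is not 348", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("corrupted NIfTI header: bad magic '", magic, "'", call. = FALSE)
  dim8 <- readBin(hdr[41:56], "integer", 8, 2, endian = endian)
  ndim <- dim8[1]
  if (ndim < 1L || ndim > 5L)
    stop("unsupported NIfTI dimensionality ", ndim, call. = FALSE)
  d <- dim8[2:(1 + ndim)]
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = endian)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pd8 <- readBin(hdr[77:108], "double", 8, 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", 1, 4, endian = endian)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    stop("corrupted NIfTI file: truncated data section", call. = FALSE)
  list(data = array(vals, d), dim = d, pixdim = pd8[2:(1 + ndim)],
       datatype = datatype)
}
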