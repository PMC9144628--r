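# Minimal MATLAB level-5 MAT-file reader/writer for numeric arrays.
# Covers what grid-electrode sEMG releases use: double/single/integer
# matrices, long and small data elements, and zlib-compressed variables.
# No installed R package reads MAT files, so this is implemented here.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_NUMERIC_CLASSES <- 6:13 # mxDOUBLE..mxUINT32

mi_size <- function(type) switch(as.character(type),
  "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
  "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L,
  stop("mat5: unsupported data type ", type))

mi_read_numeric <- function(raw, type, n) {
  sz <- mi_size(type)
  signed <- type %in% c(MI_INT8, MI_INT16, MI_INT32, MI_INT64)
  if (type %in% c(MI_INT64, MI_UINT64))
    stop("mat5: 64-bit integer data is not supported")
  if (type %in% c(MI_SINGLE, MI_DOUBLE))
    readBin(raw, "double", n = n, size = sz, endian = "little")
  else
    readBin(raw, "integer", n = n, size = sz, signed = signed, endian = "little")
}

#' Read numeric variables from a MATLAB level-5 MAT file
#'
#' Supports uncompressed and zlib-compressed data elements holding real
#' numeric arrays of any integer/float class; other variable classes are
#' skipped with a warning.
#'
#' @param path file path.
#' @return named list of numeric arrays/matrices.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128) stop("read_mat5: file too short for a MAT header")
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("read_mat5: unsupported byte order or not a level-5 MAT file")
  out <- list()
  pos <- 128L
  while (pos + 8L <= length(raw)) {
    hdr <- parse_tag(raw, pos)
    if (hdr$type == MI_COMPRESSED) {
      payload <- raw[(hdr$data_start):(hdr$data_start + hdr$size - 1L)]
      inflated <- tryCatch(memDecompress(payload, type = "gzip"),
                           error = function(e) memDecompress(payload, type = "unknown"))
      el <- parse_tag(inflated, 0L)
      v <- parse_matrix(inflated, el)
      if (!is.null(v)) out[[v$name]] <- v$value
    } else if (hdr$type == MI_MATRIX) {
      v <- parse_matrix(raw, hdr)
      if (!is.null(v)) out[[v$name]] <- v$value
    }
    pos <- hdr$next_pos
  }
  out
}

# tag at 0-based offset pos; handles the small-element format
parse_tag <- function(raw, pos) {
  u32 <- readBin(raw[(pos + 1L):(pos + 4L)], "integer", size = 4, endian = "little")
  small_size <- bitwAnd(bitwShiftR(u32, 16L), 0xFFFFL)
  if (small_size != 0L) {
    type <- bitwAnd(u32, 0xFFFFL)
    list(type = type, size = small_size, data_start = pos + 5L, next_pos = pos + 8L,
         small = TRUE)
  } else {
    size <- readBin(raw[(pos + 5L):(pos + 8L)], "integer", size = 4, endian = "little")
    padded <- if (u32 == MI_COMPRESSED) size else ((size + 7L) %/% 8L) * 8L
    list(type = u32, size = size, data_start = pos + 9L, next_pos = pos + 8L + padded,
         small = FALSE)
  }
}

parse_matrix <- function(raw, hdr) {
  if (hdr$type != MI_MATRIX) return(NULL)
  pos <- hdr$data_start - 1L # 0-based offset of the subelement stream
  end <- hdr$data_start + hdr$size - 1L
  # array flags
  t1 <- parse_tag(raw, pos)
  flags <- readBin(raw[(t1$data_start):(t1$data_start + 3L)], "integer",
                   size = 4, endian = "little")
  cls <- bitwAnd(flags, 0xFFL)
  pos <- t1$next_pos
  # dimensions
  t2 <- parse_tag(raw, pos)
  dims <- readBin(raw[(t2$data_start):(t2$data_start + t2$size - 1L)], "integer",
                  size = 4, endian = "little", n = t2$size %/% 4L)
  pos <- t2$next_pos
  # name
  t3 <- parse_tag(raw, pos)
  nm <- if (t3$size > 0)
    rawToChar(raw[(t3$data_start):(t3$data_start + t3$size - 1L)]) else ""
  pos <- t3$next_pos
  if (!(cls %in% MX_NUMERIC_CLASSES)) {
    warning("read_mat5: skipping non-numeric variable '", nm, "' (class ", cls, ")")
    return(NULL)
  }
  # real part
  t4 <- parse_tag(raw, pos)
  n <- prod(dims)
  vals <- mi_read_numeric(raw[(t4$data_start):min(t4$data_start + t4$size - 1L, end)],
                          t4$type, n)
  value <- if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else array(vals, dims)
  list(name = nm, value = value)
}

#' Write numeric arrays to a MATLAB level-5 MAT file
#'
#' Writes each element of a named list as an uncompressed double-precision
#' matrix variable.
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output file path.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by semgmeta on %s", Sys.Date())
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr) | hdr == as.raw(0)] <- charToRaw(" ")
  writeBin(hdr, con)
  writeBin(raw(8), con) # subsystem offset
  writeBin(as.integer(0x0100), con, size = 2, endian = "little")
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- if (is.null(dim(v))) c(1L, length(v)) else as.integer(dim(v))
    if (length(dims) == 1) dims <- c(1L, dims)
    name_raw <- charToRaw(nm)
    pad8 <- function(n) (8L - (n %% 8L)) %% 8L
    sz_flags <- 16L
    sz_dims <- 8L + 4L * length(dims) + pad8(4L * length(dims))
    sz_name <- 8L + length(name_raw) + pad8(length(name_raw))
    sz_data <- 8L + 8L * length(v)
    total <- sz_flags + sz_dims + sz_name + sz_data
    writeBin(c(MI_MATRIX, total), con, size = 4, endian = "little")
    # array flags: mxDOUBLE_CLASS = 6
    writeBin(c(MI_UINT32, 8L), con, size = 4, endian = "little")
    writeBin(c(6L, 0L), con, size = 4, endian = "little")
    writeBin(c(MI_INT32, 4L * length(dims)), con, size = 4, endian = "little")
    writeBin(dims, con, size = 4, endian = "little")
    writeBin(raw(pad8(4L * length(dims))), con)
    writeBin(c(MI_INT8, length(name_raw)), con, size = 4, endian = "little")
    writeBin(name_raw, con)
    writeBin(raw(pad8(length(name_raw))), con)
    writeBin(c(MI_DOUBLE, 8L * length(v)), con, size = 4, endian = "little")
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  invisible(path)
}
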