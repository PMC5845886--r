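#' @title Minimal npy (NumPy array) reader and writer
#' @description Base-R implementation of the npy v1.0 format for numeric
#' arrays: doubles are written little-endian in Fortran order (R's native
#' layout); the reader additionally accepts C-order files and the common
#' integer/float dtypes.  No pre-installed R package provides this format.
#' @name npy-io
NULL

#' Write a numeric array to an npy file
#'
#' @param x numeric vector, matrix or array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  x <- as.array(x)
  shape <- dim(x)
  shape_str <- if (length(shape) == 1L) paste0("(", shape, ",)")
               else paste0("(", paste(shape, collapse = ", "), ")")
  header <- paste0("{'descr': '<f8', 'fortran_order': True, 'shape': ",
                   shape_str, ", }")
  # pad so that magic(6) + version(2) + len(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an npy file into an R array
#'
#' @param path path to a `.npy` file.
#' @return a numeric array with the file's shape.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an npy file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1L]])
  if (length(shape) == 0L || any(is.na(shape))) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  code <- sub("^[<>|=]", "", descr)
  vals <- switch(code,
    f8 = readBin(con, "numeric", n, size = 8L, endian = "little"),
    f4 = readBin(con, "numeric", n, size = 4L, endian = "little"),
    i4 = readBin(con, "integer", n, size = 4L, endian = "little"),
    i2 = readBin(con, "integer", n, size = 2L, endian = "little"),
    i1 = readBin(con, "integer", n, size = 1L, endian = "little"),
    u1 = as.integer(readBin(con, "raw", n)),
    b1 = as.integer(readBin(con, "raw", n)),
    stop("unsupported npy dtype: ", descr))
  if (length(shape) == 0L) return(vals)
  if (fortran) {
    array(vals, shape)
  } else {
    aperm(array(vals, rev(shape)), rev(seq_along(shape)))
  }
}
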