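#' @title Minimal NPY/NPZ codec
#' @description Reads and writes numpy `.npy` arrays (float64 and integer,
#' C or Fortran order) and `.npz` archives with stored (uncompressed) entries,
#' so simulation artifacts interoperate with numpy tooling. Only the subset of
#' the format needed for numeric matrices and vectors is supported.
#' @name npz-io
NULL

npy_header <- function(shape, fortran = FALSE) {
  dict <- sprintf(
    "{'descr': '<f8', 'fortran_order': %s, 'shape': (%s), }",
    if (fortran) "True" else "False",
    if (length(shape) == 1) paste0(shape, ",") else paste(shape, collapse = ", ")
  )
  base_len <- 10L
  pad <- 64L - ((base_len + nchar(dict) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  dict <- paste0(dict, strrep(" ", pad), "\n")
  c(
    as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)),
    writeBin(nchar(dict), raw(), size = 2, endian = "little"),
    charToRaw(dict)
  )
}

npy_bytes <- function(x) {
  if (is.matrix(x)) {
    # write Fortran order; numpy reads it back with the declared flag
    c(npy_header(dim(x), fortran = TRUE),
      writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  } else {
    c(npy_header(length(x)),
      writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  }
}

#' Read a numpy `.npy` file
#'
#' @param path path to a `.npy` file (float64/int32/int64, C or Fortran order).
#' @return a numeric vector or matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  n <- prod(pmax(shape, 1L))
  x <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8, endian = "little"), # lossy past 2^53
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    stop("unsupported NPY dtype: ", descr)
  )
  if (identical(descr, "<i8")) {
    # reinterpret the doubles read above as int64 via a second pass
    con2 <- file(path, "rb")
    on.exit(close(con2), add = TRUE)
    readBin(con2, "raw", 10 + hlen)
    raw_data <- readBin(con2, "raw", n * 8)
    ints <- readBin(raw_data, "integer", n * 2, size = 4, endian = "little")
    lo <- ints[seq(1, 2 * n, 2)]
    hi <- ints[seq(2, 2 * n, 2)]
    x <- hi * 4294967296 + ifelse(lo < 0, lo + 4294967296, lo)
  }
  if (length(shape) == 2) {
    x <- if (fortran) matrix(x, shape[1], shape[2])
         else matrix(x, shape[1], shape[2], byrow = TRUE)
  }
  x
}

#' Write arrays to a numpy `.npz` archive
#'
#' Entries are stored uncompressed so the archive is written without an
#' external zip binary; numpy's `load()` reads it directly.
#'
#' @param path output path.
#' @param ... named numeric vectors/matrices.
#' @return `path`, invisibly.
#' @export
write_npz <- function(path, ...) {
  arrays <- list(...)
  if (is.null(names(arrays)) || any(names(arrays) == ""))
    stop("all npz entries must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  offset <- 0L
  for (nm in names(arrays)) {
    payload <- npy_bytes(arrays[[nm]])
    fname <- charToRaw(paste0(nm, ".npy"))
    crc <- .cpp_crc32(payload)
    sz <- length(payload)
    local_hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      writeBin(c(20L, 0L, 0L), raw(), size = 2, endian = "little"),
      writeBin(c(0L, 0L), raw(), size = 2, endian = "little"), # time, date
      u32_raw(crc),
      writeBin(c(sz, sz), raw(), size = 4, endian = "little"),
      writeBin(c(length(fname), 0L), raw(), size = 2, endian = "little"),
      fname
    )
    writeBin(local_hdr, con)
    writeBin(payload, con)
    centrals[[nm]] <- list(fname = fname, crc = crc, sz = sz, offset = offset)
    offset <- offset + length(local_hdr) + sz
  }
  cd_start <- offset
  cd_size <- 0L
  for (e in centrals) {
    hdr <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      writeBin(c(20L, 20L, 0L, 0L), raw(), size = 2, endian = "little"),
      writeBin(c(0L, 0L), raw(), size = 2, endian = "little"),
      u32_raw(e$crc),
      writeBin(c(e$sz, e$sz), raw(), size = 4, endian = "little"),
      writeBin(c(length(e$fname), 0L, 0L, 0L, 0L), raw(), size = 2, endian = "little"),
      writeBin(0L, raw(), size = 4, endian = "little"),
      u32_raw(e$offset),
      e$fname
    )
    writeBin(hdr, con)
    cd_size <- cd_size + length(hdr)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    writeBin(c(0L, 0L, length(centrals), length(centrals)), raw(), size = 2, endian = "little"),
    writeBin(c(cd_size, cd_start), raw(), size = 4, endian = "little"),
    writeBin(0L, raw(), size = 2, endian = "little")
  )
  writeBin(eocd, con)
  invisible(path)
}

# writeBin() cannot emit an unsigned 32-bit value above .Machine$integer.max,
# so CRCs are spliced in byte-wise.
u32_raw <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

#' Read arrays from a numpy `.npz` archive
#'
#' @param path path to a `.npz` file.
#' @return named list of numeric vectors/matrices.
#' @export
read_npz <- function(path) {
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  out <- lapply(files, read_npy)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}
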