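# Minimal uncompressed TIFF reader/writer.
#
# No TIFF package is available in this toolchain, so the two layouts the
# package needs are implemented directly: 32-bit IEEE float single-channel
# (probability masks) and 8-bit grayscale/RGB rasters. Little-endian
# ("II") files only for writing; both byte orders are accepted on read.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L,
               sample_format = 339L)

write_tiff_float <- function(m, path) {
  m <- as.matrix(m)
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- h * w * 4L
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")  # row-major
  entries <- list(
    c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 1L, 32L),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, 8L),
    c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, h), c(279L, 4L, 1L, data_bytes),
    c(339L, 3L, 1L, 3L))
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) {  # SHORT packed into the low bytes of the value field
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

write_tiff_rgb8 <- function(img, path) {
  img <- unclass(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.integer(round(aperm(img, c(3, 2, 1))))  # interleaved, row-major
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- h * w * 3L
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  ifd_off <- 8L + data_bytes + 6L
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.raw(px), con)
  bits_off <- 8L + data_bytes
  writeBin(c(8L, 8L, 8L), con, size = 2, endian = "little")
  entries <- list(
    c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 3L, bits_off),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 2L), c(273L, 4L, 1L, 8L),
    c(277L, 3L, 1L, 3L), c(278L, 4L, 1L, h), c(279L, 4L, 1L, data_bytes),
    c(339L, 3L, 1L, 1L))
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L && e[3] == 1L) {
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("cannot read '", path, "': truncated TIFF",
                            call. = FALSE)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("cannot read '", path, "': not a TIFF file", call. = FALSE)
  rint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)  # 4-byte offsets < 2^31
  magic <- rint(2, 2)
  if (magic != 42L) stop("cannot read '", path, "': not a TIFF file",
                         call. = FALSE)
  ifd <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  n_entries <- rint(ifd, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- rint(off, 2); type <- rint(off + 2, 2); count <- rint(off + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[type]  # BYTE, ASCII, SHORT, LONG
    if (is.na(size)) next
    if (size * count <= 4) {
      vals <- rint(off + 8, size, count)
    } else {
      voff <- rint(off + 8, 4)
      vals <- rint(voff, size, count)
    }
    tags[[as.character(tag)]] <- vals
  }
  g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
  w <- g(256); h <- g(257)
  if (is.null(w) || is.null(h))
    stop("cannot read '", path, "': missing dimensions", call. = FALSE)
  if (g(259, 1L)[1] != 1L)
    stop("cannot read '", path, "': only uncompressed TIFF is supported",
         call. = FALSE)
  bits <- g(258, 1L)[1]
  spp <- g(277, 1L)[1]
  fmt <- g(339, 1L)[1]
  offsets <- g(273); counts <- g(279, h * w * spp * bits / 8)
  buf <- raw(0)
  for (i in seq_along(offsets))
    buf <- c(buf, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
  if (fmt == 3L && bits == 32L && spp == 1L) {
    v <- readBin(buf, "numeric", n = h * w, size = 4, endian = endian)
    return(matrix(v, nrow = h, ncol = w, byrow = TRUE))
  }
  if (bits == 8L && spp %in% c(1L, 3L)) {
    v <- as.integer(buf)
    if (spp == 1L) {
      m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
      return(array(rep(m, 3L), dim = c(h, w, 3L)))
    }
    a <- aperm(array(v, dim = c(3L, w, h)), c(3, 2, 1))
    return(a)
  }
  stop("cannot read '", path, "': unsupported TIFF layout (bits=", bits,
       ", samples=", spp, ")", call. = FALSE)
}
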