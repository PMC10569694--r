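# Minimal baseline TIFF support: multi-page, single-sample, uncompressed,
# little- or big-endian, 8/16-bit unsigned integer or 32-bit float. This is
# deliberately a small self-contained implementation -- no TIFF library is
# available in the target R installation -- and covers what slice-stack
# microscopy exports actually use. Voxel size is carried the ImageJ way:
# XResolution/YResolution hold 1/dx and 1/dy, and the first page's
# ImageDescription holds "spacing=<dz>" with "unit=micron".

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a 3D volume as a multi-page TIFF
#'
#' @param data 3D numeric array `(z, y, x)`; each z-slice becomes one page.
#' @param path output file.
#' @param spacing optional `(dz, dy, dx)` um, embedded as ImageJ-style
#'   metadata (resolution tags + `spacing=` description).
#' @param bits `"auto"` (default), `8`, `16`, `"float"` (32-bit) or
#'   `"float64"`. `"auto"` picks the narrowest lossless integer type, falling
#'   back to 64-bit float so round trips are bit-exact.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path, spacing = NULL, bits = "auto") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D (z, y, x) array")
  d <- dim(data)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  rng <- range(data)
  integerish <- all(data == round(data))
  if (identical(bits, "auto")) {
    bits <- if (integerish && rng[1] >= 0 && rng[2] <= 255) 8L
            else if (integerish && rng[1] >= 0 && rng[2] <= 65535) 16L
            else "float64"
  }
  if (identical(bits, "float")) {
    bps <- 32L; fmt <- 3L; bytes_px <- 4L
  } else if (identical(bits, "float64")) {
    bps <- 64L; fmt <- 3L; bytes_px <- 8L
  } else {
    bits <- as.integer(bits)
    if (!bits %in% c(8L, 16L)) stopf("bits must be 8, 16 or \"float\"")
    if (!integerish || rng[1] < 0 || rng[2] > 2^bits - 1)
      stopf("data does not fit losslessly in unsigned %d-bit; use bits=\"float\"", bits)
    bps <- bits; fmt <- 1L; bytes_px <- bits %/% 8L
  }

  desc <- if (!is.null(spacing)) {
    spacing <- check_spacing(spacing)
    sprintf("ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%.9g\nloop=false\n",
            nz, nz, spacing[1])
  } else "lsmcount\n"
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  page_bytes <- as.numeric(ny) * nx * bytes_px
  ntags_first <- 14L; ntags_rest <- 13L
  ifd_size <- function(ntags) 2L + ntags * 12L + 4L

  off_data <- 8
  off_desc <- off_data + nz * page_bytes
  off_res <- off_desc + length(desc_raw)      # XResolution + YResolution, 16 bytes
  off_ifd1 <- off_res + 16
  ifd_off <- numeric(nz)
  cur <- off_ifd1
  for (p in seq_len(nz)) {
    ifd_off[p] <- cur
    cur <- cur + ifd_size(if (p == 1L) ntags_first else ntags_rest)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wr4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(ifd_off[1])

  # pixel data, page by page, row-major (y rows, x fastest)
  for (p in seq_len(nz)) {
    page <- as.vector(t(matrix(data[p, , ], ny, nx)))
    if (fmt == 3L) {
      writeBin(as.numeric(page), con, size = bytes_px, endian = "little")
    } else if (bps == 16L) {
      v <- as.integer(page)
      v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.raw(as.integer(page)), con)
    }
  }
  writeBin(desc_raw, con)
  # rationals: XResolution = 1/dx, YResolution = 1/dy, as num/denom with
  # denom = dx scaled to an integer
  res_rational <- function(d_um) {
    denom <- round(d_um * 1e6)
    c(1e6, denom)
  }
  xr <- if (is.null(spacing)) c(1, 1) else res_rational(spacing[3])
  yr <- if (is.null(spacing)) c(1, 1) else res_rational(spacing[2])
  wr4(xr); wr4(yr)

  tag <- function(id, type, count, value) {
    wr2(id); wr2(type); wr4(count)
    if (type == 3L && count == 1L) { wr2(value); wr2(0L) } else wr4(value)
  }
  for (p in seq_len(nz)) {
    first <- p == 1L
    wr2(if (first) ntags_first else ntags_rest)
    tag(256L, 4L, 1L, nx)                       # ImageWidth
    tag(257L, 4L, 1L, ny)                       # ImageLength
    tag(258L, 3L, 1L, bps)                      # BitsPerSample
    tag(259L, 3L, 1L, 1L)                       # Compression = none
    tag(262L, 3L, 1L, 1L)                       # Photometric = BlackIsZero
    if (first) tag(270L, 2L, length(desc_raw), off_desc)  # ImageDescription
    tag(273L, 4L, 1L, off_data + (p - 1) * page_bytes)    # StripOffsets
    tag(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                       # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)               # StripByteCounts
    tag(282L, 5L, 1L, off_res)                  # XResolution
    tag(283L, 5L, 1L, off_res + 8)              # YResolution
    tag(296L, 3L, 1L, 1L)                       # ResolutionUnit = none (ImageJ)
    tag(339L, 3L, 1L, fmt)                      # SampleFormat
    wr4(if (p < nz) ifd_off[p + 1] else 0L)     # next IFD
  }
  invisible(path)
}

#' Read a multi-page TIFF as a 3D array
#'
#' Supports the baseline uncompressed subset written by [write_tiff()] (and by
#' ImageJ/tifffile for plain grayscale stacks): strips, 8/16-bit unsigned or
#' 32-bit float, either endianness.
#'
#' @param path TIFF file.
#' @return list with `data` (3D array `(z, y, x)`) and `spacing`
#'   (`(dz, dy, dx)` um or `NULL` when the file carries no ImageJ-style
#'   calibration).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stopf("not a TIFF file: %s", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stopf("not a TIFF file: %s", path)
  rd_int <- function(off, size, n = 1L, signed = FALSE)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = if (size > 2L) TRUE else signed)
  rd_dbl <- function(off, n = 1L)
    readBin(raw[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4, endian = endian)
  if (rd_int(2, 2) != 42L) stopf("bad TIFF magic in %s", path)

  pages <- list()
  desc <- NULL; xres <- NULL; yres <- NULL
  ifd <- rd_int(4, 4)
  while (ifd != 0) {
    ntags <- rd_int(ifd, 2)
    tags <- list()
    for (i in seq_len(ntags)) {
      e <- ifd + 2 + (i - 1) * 12
      id <- rd_int(e, 2)
      type <- rd_int(e + 2, 2)
      count <- rd_int(e + 4, 4)
      size <- TIFF_TYPE_SIZE[[as.character(type)]] %||% 1L
      inline <- size * count <= 4L
      voff <- if (inline) e + 8 else rd_int(e + 8, 4)
      val <- switch(as.character(type),
        `1` = as.integer(raw[(voff + 1):(voff + count)]),
        `2` = {
          s <- raw[(voff + 1):(voff + count)]
          rawToChar(s[s != as.raw(0)])
        },
        `3` = rd_int(voff, 2, count),
        `4` = rd_int(voff, 4, count),
        `5` = {
          num <- rd_int(voff, 4, count * 2)
          num[seq(1, 2 * count, 2)] / num[seq(2, 2 * count, 2)]
        },
        NULL)
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    comp <- g(259, 1L)
    if (comp != 1L) stopf("only uncompressed TIFF is supported (compression=%d)", comp)
    if (g(277, 1L) != 1L) stopf("only single-sample (grayscale) TIFF is supported")
    nx <- g(256); ny <- g(257)
    bps <- g(258, 1L); fmt <- g(339, 1L)
    offs <- g(273); cnts <- g(279)
    if (is.null(nx) || is.null(ny) || is.null(offs))
      stopf("malformed TIFF page in %s", path)
    buf <- raw(0)
    for (k in seq_along(offs))
      buf <- c(buf, raw[(offs[k] + 1):(offs[k] + cnts[k])])
    px <- if (fmt == 3L && bps %in% c(32L, 64L)) {
      readBin(buf, "numeric", n = nx * ny, size = bps %/% 8L, endian = endian)
    } else if (bps == 16L) {
      readBin(buf, "integer", n = nx * ny, size = 2, endian = endian, signed = FALSE)
    } else if (bps == 8L) {
      as.integer(readBin(buf, "raw", n = nx * ny))
    } else stopf("unsupported TIFF bit depth %d", bps)
    pages[[length(pages) + 1L]] <- t(matrix(px, nx, ny)) # -> ny x nx
    if (is.null(desc)) desc <- g(270)
    if (is.null(xres)) xres <- g(282)
    if (is.null(yres)) yres <- g(283)
    ifd <- rd_int(ifd + 2 + ntags * 12, 4)
  }
  if (!length(pages)) stopf("TIFF contains no images: %s", path)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]

  spacing <- NULL
  if (!is.null(desc) && grepl("unit=micron", desc) && grepl("spacing=", desc) &&
      !is.null(xres) && !is.null(yres) && xres > 0 && yres > 0) {
    dz <- as.numeric(sub(".*spacing=([0-9.eE+-]+).*", "\\1", desc))
    if (is.finite(dz) && dz > 0)
      spacing <- c(dz, 1 / yres, 1 / xres)
  }
  list(data = arr, spacing = spacing)
}
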