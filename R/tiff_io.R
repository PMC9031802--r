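# Minimal baseline TIFF reader/writer (uncompressed, 8/16-bit, grayscale
# or chunky RGB, multi-page).  No image-I/O package is assumed: microscopy
# stacks used here are plain baseline TIFFs and the subset below covers
# them.  The writer emits little-endian files with one strip per page and
# records the frame rate in an ImageDescription tag ("fps=<rate>") on the
# first page; the reader accepts either byte order and multiple strips.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.tif_entry <- function(tag, type, count, value4) {
  c(.u16(tag), .u16(type), .u32(count), value4)
}
.short4 <- function(x) c(.u16(x), as.raw(c(0, 0)))

#' Write a multi-page TIFF stack
#'
#' Writes an uncompressed baseline TIFF.  Grayscale input is a 3-D array
#' (`h x w x n`); RGB input is a 4-D array (`h x w x 3 x n`).  Values are
#' rounded to integers; they must fit the requested bit depth.
#'
#' @param frames numeric array, 3-D (gray) or 4-D (RGB).
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @param fps optional frame rate, stored in the ImageDescription tag and
#'   recovered by [read_tiff_stack()].
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bits = 8, fps = NULL) {
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stop("`frames` must be a 3-D or 4-D array", call. = FALSE)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  d <- dim(frames)
  h <- d[1]; w <- d[2]
  spp <- if (nd == 4L) d[3] else 1L
  n <- d[nd]
  if (nd == 4L && spp != 3L) stop("4-D input must have 3 colour planes", call. = FALSE)
  vmax <- 2^bits - 1
  fr <- round(frames)
  if (min(fr) < 0 || max(fr) > vmax)
    stop(sprintf("pixel values outside [0, %d]", vmax), call. = FALSE)

  desc <- NULL
  if (!is.null(fps)) {
    desc <- c(charToRaw(sprintf("fps=%.9g\n", fps)), as.raw(0))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0))
  }

  bytes_px <- bits / 8L
  data_size <- h * w * spp * bytes_px
  pages <- vector("list", n)
  off <- 8L                             # running file offset
  ifd_off <- integer(n)

  for (p in seq_len(n)) {
    has_desc <- p == 1L && !is.null(desc)
    n_entries <- 9L + as.integer(has_desc)
    pad1 <- data_size %% 2L
    ifd_size <- 2L + 12L * n_entries + 4L
    ext_bps <- if (spp == 3L) 6L else 0L
    ext_desc <- if (has_desc) length(desc) else 0L

    data_off <- off
    this_ifd <- data_off + data_size + pad1
    ext_off <- this_ifd + ifd_size
    ifd_off[p] <- this_ifd
    off <- ext_off + ext_bps + ext_desc
    pages[[p]] <- list(data_off = data_off, ifd = this_ifd, ext = ext_off,
                       has_desc = has_desc, pad1 = pad1,
                       ext_bps = ext_bps, ext_desc = ext_desc)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42L), .u32(ifd_off[1])), con)

  for (p in seq_len(n)) {
    pg <- pages[[p]]
    # pixel data, row-major, channels interleaved
    if (spp == 1L) {
      vals <- as.integer(t(fr[, , p]))
    } else {
      vals <- as.integer(aperm(fr[, , , p], c(3, 2, 1)))
    }
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      writeBin(vals, con, size = 2L, endian = "little")
    }
    if (pg$pad1) writeBin(as.raw(0), con)

    bps_val <- if (spp == 1L) .short4(bits) else .u32(pg$ext)
    desc_off <- pg$ext + pg$ext_bps
    entries <- list(
      .tif_entry(256L, 4L, 1L, .u32(w)),
      .tif_entry(257L, 4L, 1L, .u32(h)),
      .tif_entry(258L, 3L, spp, bps_val),
      .tif_entry(259L, 3L, 1L, .short4(1L)),
      .tif_entry(262L, 3L, 1L, .short4(if (spp == 3L) 2L else 1L))
    )
    if (pg$has_desc)
      entries <- c(entries, list(.tif_entry(270L, 2L, length(desc), .u32(desc_off))))
    entries <- c(entries, list(
      .tif_entry(273L, 4L, 1L, .u32(pg$data_off)),
      .tif_entry(277L, 3L, 1L, .short4(spp)),
      .tif_entry(278L, 4L, 1L, .u32(h)),
      .tif_entry(279L, 4L, 1L, .u32(data_size))
    ))
    next_ifd <- if (p < n) ifd_off[p + 1] else 0L
    writeBin(c(.u16(length(entries)), do.call(c, entries), .u32(next_ifd)), con)
    if (spp == 3L) writeBin(c(.u16(bits), .u16(bits), .u16(bits)), con)
    if (pg$has_desc) writeBin(desc, con)
  }
  invisible(path)
}

.rd_uint <- function(r, off, size, endian) {
  # off is 0-based byte offset into raw vector r
  if (size == 1L) return(as.integer(r[off + 1L]))
  x <- readBin(r[(off + 1L):(off + size)], "integer", n = 1L, size = size,
               endian = endian, signed = size == 4L)
  if (size == 4L && x < 0) x <- x + 2^32
  x
}

.rd_uint_vec <- function(r, off, size, n, endian) {
  vapply(seq_len(n) - 1L, function(i) .rd_uint(r, off + i * size, size, endian), numeric(1))
}

.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L)

#' Read a multi-page TIFF stack
#'
#' Supports uncompressed baseline TIFF: 8- or 16-bit, grayscale or chunky
#' RGB, either byte order, any strip layout.  Compressed or tiled files
#' raise a format error.
#'
#' @param path TIFF file path.
#' @return list with `frames` (3-D array `h x w x n` for grayscale, 4-D
#'   `h x w x 3 x n` for RGB, raw integer values), `bits` (8 or 16) and
#'   `fps` (numeric or `NULL` if no frame rate was recorded).
#' @export
read_tiff_stack <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(r[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  if (.rd_uint(r, 2L, 2L, endian) != 42L)
    stop("not a TIFF file: ", path, call. = FALSE)

  ifd_off <- .rd_uint(r, 4L, 4L, endian)
  pages <- list()
  fps <- NULL

  while (ifd_off != 0) {
    n_entries <- .rd_uint(r, ifd_off, 2L, endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- .rd_uint(r, eo, 2L, endian)
      type <- .rd_uint(r, eo + 2L, 2L, endian)
      count <- .rd_uint(r, eo + 4L, 4L, endian)
      tsize <- .tif_type_size[as.character(type)]
      if (is.na(tsize)) next
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) eo + 8L else .rd_uint(r, eo + 8L, 4L, endian)
      if (type == 2L) {
        val <- rawToChar(r[(voff + 1L):(voff + count)][r[(voff + 1L):(voff + count)] != as.raw(0)])
      } else if (type == 5L || type == 10L) {
        val <- .rd_uint(r, voff, 4L, endian) / max(1, .rd_uint(r, voff + 4L, 4L, endian))
      } else {
        val <- .rd_uint_vec(r, voff, tsize, count, endian)
      }
      tags[[as.character(tag)]] <- val
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- .rd_uint(r, ifd_off + 2L + n_entries * 12L, 4L, endian)
  }
  if (length(pages) == 0L) stop("TIFF contains no images: ", path, call. = FALSE)

  gt <- function(tags, tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }

  first <- pages[[1]]
  w <- gt(first, 256); h <- gt(first, 257)
  if (is.null(w) || is.null(h)) stop("malformed TIFF: missing dimensions", call. = FALSE)
  bits <- unique(gt(first, 258, 1L))
  spp <- gt(first, 277, 1L)
  if (length(bits) != 1L || !bits %in% c(8, 16))
    stop("unsupported TIFF bit depth (only 8 and 16 supported)", call. = FALSE)
  if (!spp %in% c(1, 3))
    stop("unsupported TIFF sample count (only gray and RGB supported)", call. = FALSE)

  desc <- gt(first, 270)
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("fps=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) fps <- as.numeric(m[2])
  }

  n <- length(pages)
  out <- if (spp == 1) array(0, c(h, w, n)) else array(0, c(h, w, 3, n))
  for (p in seq_len(n)) {
    tg <- pages[[p]]
    if (!identical(c(gt(tg, 256), gt(tg, 257)), c(w, h)))
      stop("TIFF pages have differing dimensions", call. = FALSE)
    comp <- gt(tg, 259, 1L)
    if (comp != 1)
      stop(sprintf("unsupported TIFF compression scheme (%d); only uncompressed baseline TIFF is readable", comp), call. = FALSE)
    if (gt(tg, 284, 1L) != 1)
      stop("unsupported planar TIFF layout", call. = FALSE)
    photometric <- gt(tg, 262, 1L)
    offs <- gt(tg, 273)
    cnts <- gt(tg, 279)
    if (is.null(offs) || is.null(cnts))
      stop("malformed TIFF: missing strip layout", call. = FALSE)
    buf <- raw(sum(cnts))
    pos <- 0L
    for (s in seq_along(offs)) {
      buf[(pos + 1L):(pos + cnts[s])] <- r[(offs[s] + 1L):(offs[s] + cnts[s])]
      pos <- pos + cnts[s]
    }
    if (bits == 8) {
      vals <- as.integer(buf)
    } else {
      vals <- readBin(buf, "integer", n = length(buf) / 2L, size = 2L,
                      endian = endian, signed = FALSE)
    }
    if (length(vals) < w * h * spp)
      stop("malformed TIFF: truncated pixel data", call. = FALSE)
    vals <- vals[seq_len(w * h * spp)]
    if (!is.null(photometric) && photometric == 0) vals <- (2^bits - 1) - vals
    if (spp == 1) {
      out[, , p] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    } else {
      out[, , , p] <- aperm(array(vals, c(3, w, h)), c(3, 2, 1))
    }
  }
  list(frames = out, bits = as.integer(bits), fps = fps)
}
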