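# Minimal uncompressed AVI (RIFF) reader/writer.  Frames are stored as
# device-independent bitmaps: 8 bpp with a grayscale palette for
# single-channel video, 24 bpp BGR for colour.  Rows are bottom-up and
# padded to 4-byte boundaries, as the format requires.  Codec-compressed
# AVI cannot be decoded here and raises a format error: no codec stack is
# assumed, and lossy codecs would corrupt the frame differences this
# package analyses anyway.

.fourcc <- function(s) charToRaw(s)

.riff_chunk <- function(id, payload) {
  sz <- length(payload)
  c(.fourcc(id), .u32(sz), payload, if (sz %% 2L == 1L) as.raw(0))
}

.riff_list <- function(type, payload) .riff_chunk("LIST", c(.fourcc(type), payload))

#' Write an uncompressed AVI video
#'
#' @param frames numeric array: 3-D `h x w x n` (grayscale, written as
#'   8 bpp with a gray palette) or 4-D `h x w x 3 x n` (written as 24 bpp).
#'   Values must be integers in `[0, 255]` after rounding.
#' @param path output file path.
#' @param fps frame rate, stored in the stream header.
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps) {
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stop("`frames` must be a 3-D or 4-D array", call. = FALSE)
  d <- dim(frames)
  h <- d[1]; w <- d[2]
  rgb <- nd == 4L
  if (rgb && d[3] != 3L) stop("4-D input must have 3 colour planes", call. = FALSE)
  n <- d[nd]
  fr <- round(frames)
  if (min(fr) < 0 || max(fr) > 255) stop("pixel values outside [0, 255]", call. = FALSE)

  bpp <- if (rgb) 24L else 8L
  stride <- ((w * bpp / 8L) + 3L) %/% 4L * 4L
  frame_bytes <- stride * h

  encode_frame <- function(p) {
    if (!rgb) {
      m <- fr[, , p]
      rows <- matrix(as.raw(0), nrow = stride, ncol = h)
      rows[seq_len(w), ] <- matrix(as.raw(t(m)[, h:1]), nrow = w)
      as.vector(rows)
    } else {
      a <- fr[, , , p]
      rows <- matrix(as.raw(0), nrow = stride, ncol = h)
      # BGR interleave, bottom-up
      bgr <- aperm(a[h:1, , 3:1, drop = FALSE], c(3, 2, 1))
      rows[seq_len(3L * w), ] <- matrix(as.raw(bgr), nrow = 3L * w)
      as.vector(rows)
    }
  }

  scale <- 1000L
  rate <- as.integer(round(fps * 1000))

  bmih <- c(.u32(40L), .u32(w), .u32(h), .u16(1L), .u16(bpp), .u32(0L),
            .u32(frame_bytes), .u32(0L), .u32(0L),
            .u32(if (rgb) 0L else 256L), .u32(0L))
  palette <- if (rgb) raw(0) else as.raw(rbind(0:255, 0:255, 0:255, 0L))
  strf <- .riff_chunk("strf", c(bmih, palette))
  strh <- .riff_chunk("strh", c(
    .fourcc("vids"), .fourcc("DIB "), .u32(0L), .u16(0L), .u16(0L), .u32(0L),
    .u32(scale), .u32(rate), .u32(0L), .u32(n), .u32(frame_bytes),
    .u32(0L), .u32(0L), .u16(0L), .u16(0L), .u16(w), .u16(h)))
  avih <- .riff_chunk("avih", c(
    .u32(as.integer(round(1e6 / fps))), .u32(frame_bytes * as.integer(ceiling(fps))),
    .u32(0L), .u32(0x10L), .u32(n), .u32(0L), .u32(1L), .u32(frame_bytes),
    .u32(w), .u32(h), .u32(0L), .u32(0L), .u32(0L), .u32(0L)))
  hdrl <- .riff_list("hdrl", c(avih, .riff_list("strl", c(strh, strf))))

  chunks <- lapply(seq_len(n), function(p) .riff_chunk("00db", encode_frame(p)))
  movi <- .riff_list("movi", do.call(c, chunks))

  # idx1 offsets are relative to the first byte of the 'movi' fourcc
  offs <- 4L + cumsum(c(0L, vapply(chunks, length, integer(1))[-n]))
  idx <- do.call(c, lapply(seq_len(n), function(p) {
    c(.fourcc("00db"), .u32(0x10L), .u32(offs[p]), .u32(frame_bytes))
  }))
  idx1 <- .riff_chunk("idx1", idx)

  body <- c(.fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(.fourcc("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

#' Read an uncompressed AVI video
#'
#' Decodes BI_RGB (uncompressed) 8 bpp paletted and 24 bpp AVI streams.
#' Compressed streams raise a format error.
#'
#' @param path AVI file path.
#' @return list with `frames` (3-D grayscale array when the palette is
#'   gray, else 4-D RGB array), `bits` (always 8) and `fps` from the
#'   stream header.
#' @export
read_avi <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 12L || rawToChar(r[1:4]) != "RIFF" || rawToChar(r[9:12]) != "AVI ")
    stop("not an AVI file: ", path, call. = FALSE)

  fps <- NULL; bmih <- NULL; palette <- NULL
  frames_raw <- list()

  walk <- function(from, to) {
    pos <- from
    while (pos + 8L <= to) {
      id <- rawToChar(r[(pos + 1L):(pos + 4L)])
      sz <- .rd_uint(r, pos + 4L, 4L, "little")
      body0 <- pos + 8L
      if (id == "LIST") {
        walk(body0 + 4L, body0 + sz)
      } else if (id == "avih") {
        usec <- .rd_uint(r, body0, 4L, "little")
        if (is.null(fps) && usec > 0) fps <<- 1e6 / usec
      } else if (id == "strh") {
        typ <- rawToChar(r[(body0 + 1L):(body0 + 4L)])
        if (typ == "vids") {
          scl <- .rd_uint(r, body0 + 20L, 4L, "little")
          rte <- .rd_uint(r, body0 + 24L, 4L, "little")
          if (scl > 0 && rte > 0) fps <<- rte / scl
        }
      } else if (id == "strf" && is.null(bmih)) {
        bmih <<- list(
          width = .rd_uint(r, body0 + 4L, 4L, "little"),
          height = .rd_uint(r, body0 + 8L, 4L, "little"),
          bpp = .rd_uint(r, body0 + 14L, 2L, "little"),
          compression = .rd_uint(r, body0 + 16L, 4L, "little"),
          clr_used = .rd_uint(r, body0 + 32L, 4L, "little"))
        if (bmih$bpp == 8L) {
          ncol <- if (bmih$clr_used > 0) bmih$clr_used else 256L
          pal_off <- body0 + 40L
          palette <<- matrix(as.integer(r[(pal_off + 1L):(pal_off + 4L * ncol)]),
                             nrow = 4L)  # B, G, R, reserved
        }
      } else if (grepl("^..d[bc]$", id) && sz > 0L) {
        frames_raw[[length(frames_raw) + 1L]] <<- r[(body0 + 1L):(body0 + sz)]
      }
      pos <- body0 + sz + (sz %% 2L)
    }
  }
  walk(12L, length(r))

  if (is.null(bmih)) stop("malformed AVI: no video stream format found", call. = FALSE)
  if (bmih$compression != 0L)
    stop("compressed AVI streams are not supported; re-encode as uncompressed AVI or TIFF", call. = FALSE)
  if (length(frames_raw) == 0L) stop("AVI contains no frames", call. = FALSE)
  w <- bmih$width; h <- bmih$height

  if (bmih$bpp == 8L) {
    stride <- (w + 3L) %/% 4L * 4L
    gray_pal <- !is.null(palette) &&
      all(palette[1, ] == palette[2, ]) && all(palette[2, ] == palette[3, ])
    lut <- if (is.null(palette)) 0:255 else palette[3, ]  # red plane
    n <- length(frames_raw)
    if (gray_pal) {
      out <- array(0, c(h, w, n))
      for (p in seq_len(n)) {
        m <- matrix(as.integer(frames_raw[[p]]), nrow = stride)[seq_len(w), , drop = FALSE]
        out[, , p] <- t(m)[h:1, , drop = FALSE]
        if (!identical(lut, 0:255)) out[, , p] <- lut[out[, , p] + 1L]
      }
    } else {
      out <- array(0, c(h, w, 3, n))
      for (p in seq_len(n)) {
        m <- matrix(as.integer(frames_raw[[p]]), nrow = stride)[seq_len(w), , drop = FALSE]
        idx <- t(m)[h:1, , drop = FALSE] + 1L
        out[, , 1, p] <- matrix(palette[3, idx], h, w)
        out[, , 2, p] <- matrix(palette[2, idx], h, w)
        out[, , 3, p] <- matrix(palette[1, idx], h, w)
      }
    }
  } else if (bmih$bpp == 24L) {
    stride <- (3L * w + 3L) %/% 4L * 4L
    n <- length(frames_raw)
    out <- array(0, c(h, w, 3, n))
    for (p in seq_len(n)) {
      m <- matrix(as.integer(frames_raw[[p]]), nrow = stride)[seq_len(3L * w), , drop = FALSE]
      a <- aperm(array(m, c(3, w, h)), c(3, 2, 1))[h:1, , , drop = FALSE]  # B,G,R
      out[, , , p] <- a[, , 3:1]
    }
  } else {
    stop(sprintf("unsupported AVI bit depth (%d bpp)", bmih$bpp), call. = FALSE)
  }
  list(frames = out, bits = 8L, fps = fps)
}
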