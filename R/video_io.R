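#' Load a video into a frame stack
#'
#' Reads a multi-page TIFF or an uncompressed AVI into a [video_stack()].
#' RGB input is reduced to one plane: the green plane for
#' `channel = "green"` (the fluorescence channel of GFP-based reporters)
#' or the Rec.601 luma for `channel = "gray"`.  16-bit data are rescaled
#' linearly to `[0, 255]` using the data-type maximum (65535), not the
#' per-video maximum, so absolute intensities stay comparable across
#' recordings.
#'
#' The frame rate is taken from container metadata.  If the container
#' carries none (plain TIFF stacks often do not), an explicit
#' `fps_override` is required: every kinetic parameter downstream is in
#' seconds, so silently assuming a rate would corrupt results.
#'
#' @param path path to a `.tif`/`.tiff` or `.avi` file.
#' @param channel `"green"` (default) or `"gray"`; which plane to extract
#'   from RGB input.  Single-plane input is used as-is and labelled with
#'   the requested channel.
#' @param fps_override optional frame rate overriding (or supplying)
#'   container metadata.
#' @return a [video_stack()].
#' @export
load_video <- function(path, channel = c("green", "gray"), fps_override = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = read_tiff_stack(path),
    avi = read_avi(path),
    stop("unrecognized video format '.", ext,
         "'; supported: multi-page TIFF, uncompressed AVI", call. = FALSE)
  )

  fps <- if (!is.null(fps_override)) fps_override else raw$fps
  if (is.null(fps))
    stop("no frame rate in container metadata; supply `fps_override` ",
         "(kinetic parameters are reported in seconds)", call. = FALSE)

  fr <- raw$frames
  if (length(dim(fr)) == 4L) {
    fr <- if (channel == "green") {
      fr[, , 2, , drop = TRUE]
    } else {
      0.299 * fr[, , 1, , drop = TRUE] + 0.587 * fr[, , 2, , drop = TRUE] +
        0.114 * fr[, , 3, , drop = TRUE]
    }
    if (length(dim(fr)) != 3L) fr <- array(fr, dim(raw$frames)[c(1, 2, 4)])
  }
  if (length(dim(fr)) != 3L || dim(fr)[3] < 2L)
    stop("insufficient frames: a video needs at least 2 frames", call. = FALSE)
  if (raw$bits == 16L) fr <- fr * (255 / 65535)

  video_stack(fr, fps = fps, channel = channel)
}

#' Write a video stack to disk
#'
#' Dispatches on file extension: `.tif`/`.tiff` writes a multi-page
#' baseline TIFF (with the frame rate recorded in the image description),
#' `.avi` an uncompressed 8 bpp AVI.
#'
#' @param stack a [video_stack()].
#' @param path output path ending in `.tif`, `.tiff` or `.avi`.
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path) {
  stopifnot(inherits(stack, "video_stack"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = write_tiff_stack(stack$frames, path, bits = 8, fps = stack$fps),
    avi = write_avi(stack$frames, path, fps = stack$fps),
    stop("unrecognized video format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Load a one-column CSV trace
#'
#' Reads a single-column numeric CSV (optional header) into a
#' [time_series()], for trace-only analysis when the original video is
#' unavailable.
#'
#' @param path CSV path, one numeric value per row.
#' @param dt seconds per sample.
#' @return a [time_series()].
#' @export
load_trace <- function(path, dt) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("trace parse error: file is empty", call. = FALSE)

  first <- suppressWarnings(as.numeric(lines[1]))
  start <- if (is.na(first)) 2L else 1L       # tolerate one header row
  if (start > length(lines))
    stop("trace parse error: no numeric rows", call. = FALSE)
  body <- lines[start:length(lines)]
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals))
  if (length(bad) > 0L)
    stop(sprintf("trace parse error: non-numeric value at row %d ('%s')",
                 bad[1] + start - 1L, body[bad[1]]), call. = FALSE)
  time_series(vals, dt)
}

#' Write a time series to CSV
#'
#' Writes two columns, `time_s` and `value`; readable back with
#' [load_trace()] is not intended (that loader takes one column), this is
#' the human/report-facing format.
#'
#' @param trace a [time_series()].
#' @param path output CSV path.
#' @param value_name column name for the values.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, value_name = "value") {
  df <- data.frame(time_s = trace_times(trace), v = trace$values)
  names(df)[2] <- value_name
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
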