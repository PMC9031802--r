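#' Video stack container
#'
#' An ordered stack of 2-D intensity frames with a frame rate.  Pixel
#' values are kept on the 8-bit scale (0--255); 16-bit input is rescaled
#' on load.  This is the common currency of the whole pipeline.
#'
#' @param frames numeric array `height x width x n_frames`, values in
#'   `[0, 255]`, all finite.
#' @param fps frames per second (must be `> 0`).
#' @param channel which colour plane the stack holds: `"green"` or
#'   `"gray"`.
#' @return An object of class `video_stack`: a list with elements
#'   `frames`, `height`, `width`, `fps`, `channel`.
#' @export
video_stack <- function(frames, fps, channel = c("gray", "green")) {
  channel <- match.arg(channel)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (height x width x frames)", call. = FALSE)
  d <- dim(frames)
  if (d[3] < 2L)
    stop("insufficient frames: a video needs at least 2 frames", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (anyNA(frames) || !all(is.finite(frames)))
    stop("frames contain non-finite pixel values", call. = FALSE)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255] (rescale on load)", call. = FALSE)
  structure(
    list(frames = frames, height = d[1], width = d[2],
         fps = fps, channel = channel),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  cat(sprintf("<video_stack> %d frames, %d x %d px, %.3g fps, channel=%s\n",
              n_frames(x), x$height, x$width, x$fps, x$channel))
  invisible(x)
}

#' Number of frames in a video stack
#' @param stack a [video_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack a [video_stack()].
#' @param i frame index (1-based).
#' @return `height x width` numeric matrix.
#' @export
get_frame <- function(stack, i) stack$frames[, , i]

#' Regularly sampled time series
#'
#' Carrier for velocity and intensity traces: an ordered numeric vector
#' with a fixed sampling interval.
#'
#' @param values numeric vector (length >= 1).
#' @param dt seconds per sample (`1/fps` for frame-derived series).
#' @return An object of class `time_series`: list with `values`, `dt`.
#' @export
time_series <- function(values, dt) {
  if (length(values) < 1L) stop("time series must have length >= 1", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  structure(list(values = as.numeric(values), dt = dt), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<%s> %d samples, dt = %.5g s (%.4g s total)\n",
              class(x)[1], length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

# Accept either a time_series or a bare numeric vector.
trace_values <- function(trace) {
  if (inherits(trace, "time_series")) trace$values else as.numeric(trace)
}

#' Times of the samples in a time series
#' @param trace a [time_series()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
trace_times <- function(trace) (seq_along(trace$values) - 1) * trace$dt
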