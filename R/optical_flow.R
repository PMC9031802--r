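#' Horn-Schunck dense optical flow between two frames
#'
#' Estimates the displacement field mapping `prev` onto `next` under
#' brightness constancy with a global smoothness penalty, iterated with
#' the classical Jacobi scheme and the standard 3x3 local-average kernel
#' (1/6 edge, 1/12 diagonal weights).  Spatial/temporal derivatives use
#' the original forward 2x2x2 stencils with replicated borders.
#'
#' Frames are divided by 255 before the computation, so `alpha` is always
#' interpreted on a `[0, 1]` intensity scale regardless of input bit
#' depth.  The default `alpha = 0.1` (roughly 25 intensity levels on the
#' 8-bit scale) damps the spurious flow that camera noise induces at
#' low-gradient pixels -- important because the downstream top-fraction
#' statistic looks only at the extreme tail of the field.  For precise
#' sub-pixel registration of clean, well-textured frames, `alpha = 0.05`
#' or lower is more accurate; larger values bias speeds low.
#'
#' @param prev,next_ numeric matrices of identical shape (intensities on
#'   the 0--255 scale).
#' @param alpha smoothness weight (> 0), on the `[0, 1]` intensity scale.
#' @param n_iter iteration cap (>= 1).
#' @param tol convergence tolerance on the mean absolute update of the
#'   flow components, in pixels.
#' @return An object of class `flow_field`: list with matrices `u`
#'   (displacement along columns, +x rightward) and `v` (along rows,
#'   +y downward) in pixels per frame interval, plus `iterations` and
#'   `converged`.
#' @export
horn_schunck <- function(prev, next_, alpha = 0.1, n_iter = 400, tol = 1e-4) {
  if (!is.matrix(prev) || !is.matrix(next_))
    stop("frames must be matrices", call. = FALSE)
  if (!identical(dim(prev), dim(next_)))
    stop("frame dimension mismatch: ", paste(dim(prev), collapse = "x"),
         " vs ", paste(dim(next_), collapse = "x"), call. = FALSE)
  if (anyNA(prev) || anyNA(next_) || !all(is.finite(prev)) || !all(is.finite(next_)))
    stop("frames contain non-finite pixel values", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)

  res <- hs_flow_cpp(prev / 255, next_ / 255, alpha, as.integer(n_iter), tol)
  structure(res, class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d px, %d iterations%s, max |flow| = %.4g px\n",
              nrow(x$u), ncol(x$u), x$iterations,
              if (x$converged) " (converged)" else "",
              max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Top-fraction speed of a flow field
#'
#' Reduces a dense flow field to one scalar: per-pixel magnitudes
#' `sqrt(u^2 + v^2)` are ranked and the `k = max(1, floor(fraction * N))`
#' largest are aggregated.  The default fraction of 1/3000 keeps only the
#' fastest-moving pixels -- in a cardiomyocyte recording these sit on the
#' moving sarcomere pattern, so the statistic tracks peak tissue velocity
#' rather than the (mostly static) full field average.
#'
#' @param field a [horn_schunck()] `flow_field`, or a list with matrices
#'   `u` and `v`.
#' @param fraction proportion of pixels to keep, in `(0, 1]`.
#' @param reduce statistic over the top-k magnitudes: `"mean"` (default),
#'   `"min"` or `"max"`.
#' @return scalar speed in pixels per frame interval.
#' @export
top_fraction_speed <- function(field, fraction = 1 / 3000,
                               reduce = c("mean", "min", "max")) {
  reduce <- match.arg(reduce)
  if (is.null(field$u) || length(field$u) == 0L)
    stop("empty flow field", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  mag <- sqrt(field$u^2 + field$v^2)
  n <- length(mag)
  k <- max(1L, floor(fraction * n))
  top <- sort(mag, decreasing = TRUE)[seq_len(k)]
  switch(reduce, mean = mean(top), min = min(top), max = max(top))
}

#' Per-frame-pair velocity trace of a video
#'
#' Applies [horn_schunck()] to each consecutive frame pair and
#' [top_fraction_speed()] to each field, then converts pixels/frame to
#' pixels/second by multiplying with the frame rate.  The result has one
#' sample per frame pair (`n_frames - 1`).
#'
#' @param stack a [video_stack()] with >= 2 frames.
#' @inheritParams horn_schunck
#' @inheritParams top_fraction_speed
#' @return A `velocity_trace` (subclass of [time_series()]): values in
#'   pixels/s, `dt = 1/fps`, with the fraction kept as attribute
#'   `fraction`.
#' @export
velocity_trace <- function(stack, alpha = 0.1, n_iter = 400, tol = 1e-4,
                           fraction = 1 / 3000,
                           reduce = c("mean", "min", "max")) {
  stopifnot(inherits(stack, "video_stack"))
  reduce <- match.arg(reduce)
  n <- n_frames(stack)
  vals <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    fl <- horn_schunck(get_frame(stack, i), get_frame(stack, i + 1L),
                       alpha = alpha, n_iter = n_iter, tol = tol)
    vals[i] <- top_fraction_speed(fl, fraction = fraction, reduce = reduce)
  }
  out <- time_series(vals * stack$fps, dt = 1 / stack$fps)
  attr(out, "fraction") <- fraction
  class(out) <- c("velocity_trace", class(out))
  out
}
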