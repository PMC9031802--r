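#' Subtract static background from a video
#'
#' The per-pixel temporal minimum over the whole recording is subtracted
#' from every frame (negative results clamp to zero).  For an additive
#' static background this is exact, needs no user-drawn ROI, and is
#' idempotent.  A percentile variant (`method = "percentile"`, with `p`)
#' is available for recordings whose darkest frame still carries signal
#' everywhere.
#'
#' @param stack a [video_stack()] (green channel for calcium analysis).
#' @param method `"temporal_min"` (default) or `"percentile"`.
#' @param p percentile (0--100) used when `method = "percentile"`.
#' @return a background-subtracted [video_stack()].
#' @export
subtract_background <- function(stack, method = c("temporal_min", "percentile"),
                                p = 5) {
  stopifnot(inherits(stack, "video_stack"))
  method <- match.arg(method)
  bg <- if (method == "temporal_min") {
    apply(stack$frames, c(1, 2), min)
  } else {
    apply(stack$frames, c(1, 2), quantile, probs = p / 100, type = 7, names = FALSE)
  }
  fr <- sweep(stack$frames, c(1, 2), bg, `-`)
  fr[fr < 0] <- 0
  video_stack(fr, fps = stack$fps, channel = stack$channel)
}

#' Mean green intensity trace of a recording
#'
#' Per frame, the mean intensity over pixels with value > 0 (zero pixels
#' are excluded so that the dark, cell-free background does not dilute
#' the fluorescence signal; a frame with no nonzero pixel contributes 0).
#'
#' With `normalize = "max255"` the series is then rescaled so its maximum
#' equals 255.  The default is `"none"`: the trace stays on the raw 8-bit
#' scale, so the amplitude and maximal slope remain comparable *between*
#' recordings -- per-recording rescaling would cancel exactly the
#' amplitude differences that the maximal upstroke slope is used to
#' detect (inotropic effects).  See the methods vignette.
#'
#' @param stack a background-subtracted [video_stack()].
#' @param normalize `"none"` (default) or `"max255"`.
#' @param baseline_percentile percentile defining the trace baseline.
#' @return A `calcium_trace` (subclass of [time_series()]) with
#'   attributes `baseline` (the percentile level) and `flagged` (`TRUE`
#'   for an all-zero recording, where normalization is skipped).
#' @export
intensity_trace <- function(stack, normalize = c("none", "max255"),
                            baseline_percentile = 10) {
  stopifnot(inherits(stack, "video_stack"))
  normalize <- match.arg(normalize)
  n <- n_frames(stack)
  vals <- vapply(seq_len(n), function(i) {
    f <- stack$frames[, , i]
    nz <- f[f > 0]
    if (length(nz) == 0L) 0 else mean(nz)
  }, numeric(1))

  flagged <- max(vals) == 0
  if (!flagged && normalize == "max255") vals <- vals * (255 / max(vals))

  out <- time_series(vals, dt = 1 / stack$fps)
  attr(out, "baseline") <- trace_baseline(vals, baseline_percentile)
  attr(out, "flagged") <- flagged
  attr(out, "normalize") <- normalize
  class(out) <- c("calcium_trace", class(out))
  out
}

#' Calcium spark series from frame differences
#'
#' Brief localized fluorescence rises (calcium sparks) are detected from
#' the difference between successive frames: `diff = next - prev`,
#' clamped below at zero (only intensity rises count), then thresholded
#' at a fixed minimum difference (default 10 on the 8-bit scale -- an
#' absolute threshold, deliberately not scale-invariant).  Per frame
#' pair:
#'
#' * `sp_area`: fraction of the image area where `diff >= threshold`;
#' * `sp_intensity`: mean of `diff` over that area (0 when empty),
#'   optionally rescaled so the series maximum is 255.
#'
#' @param stack a background-subtracted [video_stack()].
#' @param threshold minimum difference counted as a spark (> 0,
#'   inclusive comparison).
#' @param normalize `"max255"` (default) rescales `sp_intensity` so its
#'   maximum is 255; `"none"` keeps raw mean differences.  Skipped and
#'   flagged when the series is all zero.
#' @return An object of class `spark_series`: list with numeric vectors
#'   `sp_intensity` and `sp_area` (length `n_frames - 1`), `dt`,
#'   `threshold`, and `flagged`.
#' @export
spark_series <- function(stack, threshold = 10,
                         normalize = c("max255", "none")) {
  stopifnot(inherits(stack, "video_stack"))
  normalize <- match.arg(normalize)
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  n <- n_frames(stack)
  npx <- stack$height * stack$width
  sp_i <- sp_a <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- stack$frames[, , i + 1L] - stack$frames[, , i]
    d[d < 0] <- 0
    mask <- d >= threshold
    k <- sum(mask)
    sp_a[i] <- k / npx
    sp_i[i] <- if (k > 0L) mean(d[mask]) else 0
  }
  flagged <- max(sp_i) == 0
  if (!flagged && normalize == "max255") sp_i <- sp_i * (255 / max(sp_i))
  structure(list(sp_intensity = sp_i, sp_area = sp_a, n_pixels = npx,
                 dt = 1 / stack$fps, threshold = threshold, flagged = flagged),
            class = "spark_series")
}

#' @export
print.spark_series <- function(x, ...) {
  cat(sprintf("<spark_series> %d frame pairs, threshold %g, max area %.3g\n",
              length(x$sp_area), x$threshold, max(x$sp_area)))
  invisible(x)
}

# Spark-intensity peaks: same local-maximum machinery as the velocity
# path, with baseline 0 and a relative 5% amplitude filter.  A minimum
# spark area (in pixels, at the apex sample) additionally rejects
# single-pixel noise crossings of the absolute difference threshold --
# genuine sparks are multi-pixel events.
spark_peaks <- function(sparks, min_rel_amplitude = 0.05, min_area_px = 4) {
  v <- sparks$sp_intensity
  if (all(v == 0)) return(integer(0))
  pk <- detect_peaks(v, baseline = 0, min_rel_amplitude = min_rel_amplitude,
                     endpoint_frac = 0.5)
  apex <- pk$apex
  npx <- if (is.null(sparks$n_pixels)) Inf else sparks$n_pixels
  apex[sparks$sp_area[apex] * npx >= min_area_px]
}

#' Per-transient calcium kinetics
#'
#' Detects fluorescence transients on a calcium trace (peak rules as in
#' [detect_peaks()], with endpoints at 10% of the amplitude above
#' baseline) and reports, per transient:
#'
#' * `t0_s`: time of the sample immediately before the rise (the start
#'   endpoint);
#' * `ttp_s`: time from `t0` to the transient maximum;
#' * `t90_s`: time for the signal to return from its maximum to 10% of
#'   the amplitude above baseline (`NA` and flagged when the trace never
#'   gets there before the next transient or the trace end);
#' * `amplitude`: peak minus baseline;
#' * `width10_s`: peak width at 10% height above baseline;
#' * `dfdt_max`: largest single-frame-interval intensity rise on the
#'   rising edge, divided by the frame interval (the inotropy readout);
#' * `spark_count_before`: number of spark-intensity peaks strictly
#'   between the previous transient's end (or the trace start) and this
#'   transient's `t0`.
#'
#' @param trace a `calcium_trace` (or any [time_series()]).
#' @param sparks optional [spark_series()]; when `NULL`,
#'   `spark_count_before` is `NA`.
#' @param baseline_percentile percentile defining the baseline.
#' @param width_height_frac endpoint height fraction (default 0.10).
#' @param min_rel_amplitude relative amplitude filter (default 0.05).
#' @param spark_min_area_px minimum spark area (pixels) for a
#'   spark-intensity peak to be counted; rejects single-pixel noise
#'   crossings of the absolute difference threshold.
#' @return data frame, one row per transient, columns `t0_s`, `ttp_s`,
#'   `t90_s`, `amplitude`, `width10_s`, `dfdt_max`, `spark_count_before`,
#'   `t90_truncated`.  Empty (zero rows) when no transient qualifies.
#' @export
transient_metrics <- function(trace, sparks = NULL, baseline_percentile = 10,
                              width_height_frac = 0.10,
                              min_rel_amplitude = 0.05,
                              spark_min_area_px = 4) {
  v <- trace_values(trace)
  if (length(v) < 3L) stop("trace too short (need >= 3 samples)", call. = FALSE)
  dt <- if (inherits(trace, "time_series")) trace$dt else
    stop("`trace` must be a time_series", call. = FALSE)

  bl <- trace_baseline(v, baseline_percentile)
  pk <- detect_peaks(v, baseline = bl, min_rel_amplitude = min_rel_amplitude,
                     endpoint_frac = width_height_frac)
  if (nrow(pk) == 0L) {
    return(data.frame(t0_s = numeric(0), ttp_s = numeric(0), t90_s = numeric(0),
                      amplitude = numeric(0), width10_s = numeric(0),
                      dfdt_max = numeric(0), spark_count_before = numeric(0),
                      t90_truncated = logical(0)))
  }

  sp_apex <- if (!is.null(sparks))
    spark_peaks(sparks, min_area_px = spark_min_area_px) else NULL

  out <- lapply(seq_len(nrow(pk)), function(i) {
    t90 <- if (pk$truncated_right[i]) NA_real_ else (pk$end[i] - pk$apex[i]) * dt
    n_sp <- NA_real_
    if (!is.null(sp_apex)) {
      # spark sample j is the rise into frame j+1; count sparks whose
      # frame lies strictly between the previous transient's end and t0
      prev_end <- if (i > 1L) pk$end[i - 1L] else 0L
      spark_frame <- sp_apex + 1L
      n_sp <- sum(spark_frame > prev_end & spark_frame < pk$start[i])
    }
    data.frame(
      t0_s = (pk$start[i] - 1L) * dt,
      ttp_s = (pk$apex[i] - pk$start[i]) * dt,
      t90_s = t90,
      amplitude = pk$amplitude[i],
      width10_s = (pk$end[i] - pk$start[i]) * dt,
      dfdt_max = max_rise(v, pk$start[i], pk$apex[i], dt),
      spark_count_before = n_sp,
      t90_truncated = pk$truncated_right[i])
  })
  do.call(rbind, out)
}

#' Summarize calcium transients
#'
#' Per-recording summary of [transient_metrics()] output: transient
#' count, rate, and mean +/- SEM of each kinetic parameter (`NA` values,
#' e.g. truncated T90, are dropped per metric).
#'
#' @param transients data frame from [transient_metrics()].
#' @param duration_s analysed duration in seconds.
#' @return list of class `calcium_summary` with `n_transients`,
#'   `rate_hz`, and a `metrics` data frame (`metric`, `mean`, `sem`).
#' @export
summarize_transients <- function(transients, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  cols <- c("ttp_s", "t90_s", "amplitude", "width10_s", "dfdt_max",
            "spark_count_before")
  n <- nrow(transients)
  metrics <- if (n > 0L) {
    data.frame(
      metric = cols,
      mean = vapply(cols, function(m) {
        x <- transients[[m]][!is.na(transients[[m]])]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1)),
      sem = vapply(cols, function(m) sem(transients[[m]][!is.na(transients[[m]])]),
                   numeric(1)),
      row.names = NULL)
  } else {
    data.frame(metric = character(0), mean = numeric(0), sem = numeric(0))
  }
  structure(list(n_transients = n, rate_hz = n / duration_s,
                 duration_s = duration_s, metrics = metrics),
            class = "calcium_summary")
}

#' @export
print.calcium_summary <- function(x, ...) {
  cat(sprintf("<calcium_summary> %d transients in %.3g s (%.3g Hz)\n",
              x$n_transients, x$duration_s, x$rate_hz))
  if (nrow(x$metrics)) print(x$metrics, row.names = FALSE)
  invisible(x)
}
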