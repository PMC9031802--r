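#' Trace baseline by percentile
#'
#' The baseline of a physiological trace is defined as a low percentile
#' of its values (default the 10th), computed with linear interpolation
#' between order statistics (R's quantile type 7).
#'
#' @param trace a [time_series()] or numeric vector.
#' @param percentile percentile in `[0, 100]` (default 10).
#' @return scalar baseline level, in trace units.
#' @export
trace_baseline <- function(trace, percentile = 10) {
  v <- trace_values(trace)
  if (length(v) == 0L) stop("empty trace", call. = FALSE)
  if (percentile < 0 || percentile > 100)
    stop("`percentile` must be in [0, 100]", call. = FALSE)
  unname(quantile(v, percentile / 100, type = 7, names = FALSE))
}

# Local maxima: strictly greater than both neighbouring distinct values;
# plateaus contribute their centre sample (left-centre on even lengths);
# boundary runs have only one neighbour and are never maxima.
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  j <- j[is_max]
  as.integer(starts[j] + (r$lengths[j] - 1L) %/% 2L)
}

# Outward scan from the apex for the first crossing of `level`, bounded
# by `bound` (adjacent retained apex or trace end).  The fractional
# crossing index is linearly interpolated and rounded to the nearest
# sample.  Returns c(index, truncated_flag).
scan_crossing <- function(v, apex, level, bound, direction) {
  step <- if (direction == "right") 1L else -1L
  j <- apex
  while ((j + step) * step <= bound * step) {
    nxt <- j + step
    if (v[nxt] <= level) {
      frac <- (v[j] - level) / (v[j] - v[nxt])   # in (0, 1]
      idx <- as.integer(round(j + step * frac))
      return(c(idx, 0L))
    }
    j <- nxt
  }
  c(bound, 1L)
}

#' Detect peaks in a trace
#'
#' Implements the velocity/fluorescence peak rules used throughout the
#' pipeline:
#'
#' 1. candidate apexes are local maxima lying above the baseline
#'    (strictly greater than both neighbours; plateaus take their centre
#'    sample);
#' 2. candidates whose amplitude (apex minus baseline) is below
#'    `min_rel_amplitude` times the largest amplitude in the trace are
#'    discarded -- the filter is relative, so it is invariant to scaling;
#' 3. each surviving peak's start and end are placed at the first points
#'    on either side of the apex where the trace falls back to
#'    `baseline + endpoint_frac * amplitude` (20% above baseline for
#'    velocity peaks, 10% for calcium transients), found by outward scan
#'    with linear interpolation, rounded to the nearest sample.  If the
#'    trace never falls to that level before the trace boundary or the
#'    neighbouring peak's apex, the endpoint is truncated there and
#'    flagged.
#'
#' @param trace a [time_series()] or numeric vector.
#' @param baseline baseline level; default the 10th percentile of the
#'   trace ([trace_baseline()]).
#' @param min_rel_amplitude relative amplitude threshold in `(0, 1)`
#'   (default 0.05, the 5% rule).
#' @param endpoint_frac endpoint level as a fraction of the peak
#'   amplitude above baseline, in `(0, 1)` (default 0.20).
#' @return A `peak_table`: data frame with one row per peak and columns
#'   `start`, `apex`, `end` (sample indices), `amplitude`, `baseline`,
#'   `truncated_left`, `truncated_right`.  A trace with no qualifying
#'   peaks yields zero rows, not an error.
#' @export
detect_peaks <- function(trace, baseline = NULL, min_rel_amplitude = 0.05,
                         endpoint_frac = 0.20) {
  v <- trace_values(trace)
  if (min_rel_amplitude <= 0 || min_rel_amplitude >= 1)
    stop("`min_rel_amplitude` must be in (0, 1)", call. = FALSE)
  if (endpoint_frac <= 0 || endpoint_frac >= 1)
    stop("`endpoint_frac` must be in (0, 1)", call. = FALSE)
  if (is.null(baseline)) baseline <- trace_baseline(v)

  empty <- data.frame(start = integer(0), apex = integer(0), end = integer(0),
                      amplitude = numeric(0), baseline = numeric(0),
                      truncated_left = logical(0), truncated_right = logical(0))
  class(empty) <- c("peak_table", "data.frame")

  apexes <- local_maxima(v)
  apexes <- apexes[v[apexes] > baseline]
  if (length(apexes) == 0L) return(empty)
  amp <- v[apexes] - baseline
  keep <- amp >= min_rel_amplitude * max(amp)
  apexes <- apexes[keep]
  amp <- amp[keep]
  if (length(apexes) == 0L) return(empty)

  n <- length(v)
  m <- length(apexes)
  start <- end <- integer(m)
  tl <- tr <- logical(m)
  for (i in seq_len(m)) {
    level <- baseline + endpoint_frac * amp[i]
    lbound <- if (i > 1L) apexes[i - 1L] else 1L
    rbound <- if (i < m) apexes[i + 1L] else n
    left <- scan_crossing(v, apexes[i], level, lbound, "left")
    right <- scan_crossing(v, apexes[i], level, rbound, "right")
    start[i] <- left[1]; tl[i] <- left[2] == 1L
    end[i] <- right[1]; tr[i] <- right[2] == 1L
  }
  out <- data.frame(start = start, apex = apexes, end = end,
                    amplitude = amp, baseline = baseline,
                    truncated_left = tl, truncated_right = tr)
  class(out) <- c("peak_table", "data.frame")
  out
}

# Largest single-interval forward rise between samples `from` and `to`,
# divided by dt.  NA when the window has no interval.
max_rise <- function(v, from, to, dt) {
  if (to <= from) return(NA_real_)
  max(diff(v[from:to])) / dt
}

#' Pair velocity peaks into contraction/relaxation events
#'
#' A beating cardiomyocyte produces two velocity peaks per beat: one
#' during sarcomere shortening (contraction) and one during
#' re-lengthening (relaxation).  Peaks are matched greedily left to
#' right: peak *i* and peak *i+1* form an event when the start of
#' *i+1* follows the end of *i* by at most `max_gap_s` seconds; matched
#' peaks are consumed, so no peak belongs to two events.  The first peak
#' of a pair is taken as the contraction, the second as the relaxation.
#'
#' Per event, the delay (relaxation start minus contraction end, clamped
#' at zero when truncated endpoints overlap), the contraction and
#' relaxation durations (between the peak endpoints), the time-to-peak of
#' the contraction, and the maximal single-interval slope on the
#' contraction rising edge are computed.
#'
#' @param trace the [time_series()] (or numeric vector) the peaks were
#'   detected on; needed for the rising-edge slope.
#' @param peaks a `peak_table` from [detect_peaks()], ordered by apex.
#' @param max_gap_s largest allowed gap between the end of a contraction
#'   peak and the start of the following relaxation peak, in seconds
#'   (default 0.1 s = 5 frames at 50 fps).
#' @param dt seconds per sample; defaults to `trace$dt` when `trace` is a
#'   [time_series()].
#' @return list with `events` (data frame, one row per event:
#'   `c_start`, `c_apex`, `c_end`, `r_start`, `r_apex`, `r_end` sample
#'   indices, `delay_s`, `ttp_s`, `dfdt_max`, `contraction_time_s`,
#'   `relaxation_time_s`) and `unmatched` (row indices into `peaks` of
#'   peaks in no event).
#' @export
pair_events <- function(trace, peaks, max_gap_s = 0.1, dt = NULL) {
  v <- trace_values(trace)
  if (is.null(dt)) {
    if (!inherits(trace, "time_series"))
      stop("`dt` must be given when `trace` is not a time_series", call. = FALSE)
    dt <- trace$dt
  }
  m <- nrow(peaks)
  ev <- list()
  unmatched <- integer(0)
  i <- 1L
  while (i <= m) {
    if (i < m) {
      gap_s <- (peaks$start[i + 1L] - peaks$end[i]) * dt
      if (gap_s <= max_gap_s) {
        ev[[length(ev) + 1L]] <- data.frame(
          c_start = peaks$start[i], c_apex = peaks$apex[i], c_end = peaks$end[i],
          r_start = peaks$start[i + 1L], r_apex = peaks$apex[i + 1L],
          r_end = peaks$end[i + 1L],
          delay_s = max(gap_s, 0),
          ttp_s = (peaks$apex[i] - peaks$start[i]) * dt,
          dfdt_max = max_rise(v, peaks$start[i], peaks$apex[i], dt),
          contraction_time_s = (peaks$end[i] - peaks$start[i]) * dt,
          relaxation_time_s = (peaks$end[i + 1L] - peaks$start[i + 1L]) * dt
        )
        i <- i + 2L
        next
      }
    }
    unmatched <- c(unmatched, i)
    i <- i + 1L
  }
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    c_start = integer(0), c_apex = integer(0), c_end = integer(0),
    r_start = integer(0), r_apex = integer(0), r_end = integer(0),
    delay_s = numeric(0), ttp_s = numeric(0), dfdt_max = numeric(0),
    contraction_time_s = numeric(0), relaxation_time_s = numeric(0))
  list(events = events, unmatched = unmatched)
}

sem <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))

#' Summarize contraction/relaxation events
#'
#' Per-recording summary: number of events, beating rate (events per
#' second of analysed trace) and mean +/- SEM of each per-event metric.
#' SEM is the sample standard deviation over the square root of the
#' event count; it is `NA` with fewer than two events.
#'
#' @param events event data frame from [pair_events()].
#' @param duration_s analysed duration in seconds (> 0).
#' @return An object of class `kinetics_summary`: list with `n_events`,
#'   `beat_rate_hz` and a data frame `metrics` (columns `metric`, `mean`,
#'   `sem`).  With zero events the rate is 0 and `metrics` has zero rows.
#' @export
summarize_kinetics <- function(events, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events))
    events <- events$events
  metric_cols <- c("ttp_s", "dfdt_max", "contraction_time_s",
                   "relaxation_time_s", "delay_s")
  n <- nrow(events)
  metrics <- if (n > 0L) {
    data.frame(
      metric = metric_cols,
      mean = vapply(metric_cols, function(m) mean(events[[m]]), numeric(1)),
      sem = vapply(metric_cols, function(m) sem(events[[m]]), numeric(1)),
      row.names = NULL)
  } else {
    data.frame(metric = character(0), mean = numeric(0), sem = numeric(0))
  }
  structure(list(n_events = n, beat_rate_hz = n / duration_s,
                 duration_s = duration_s, metrics = metrics),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics_summary> %d events in %.3g s (%.3g Hz)\n",
              x$n_events, x$duration_s, x$beat_rate_hz))
  if (nrow(x$metrics)) print(x$metrics, row.names = FALSE)
  invisible(x)
}
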