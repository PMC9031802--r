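#' Pipeline configuration
#'
#' Returns the fully materialized analysis configuration: the documented
#' defaults of every stage, deep-merged with overrides from a JSON file
#' and/or from a named list.  `analyze()` writes the resolved
#' configuration next to its outputs so every run is reproducible.
#'
#' Sections and defaults:
#' * `flow`: `alpha = 0.1`, `iterations = 400`, `tolerance = 1e-4`,
#'   `fraction = 1/3000`, `reduce = "mean"`;
#' * `peaks`: `min_rel_amplitude = 0.05`, `baseline_percentile = 10`,
#'   `endpoint_frac = 0.20`, `max_gap_s = 0.1`;
#' * `calcium`: `spark_threshold = 10`, `width_height_frac = 0.10`,
#'   `baseline_percentile = 10`, `background = "temporal_min"`,
#'   `normalize = "none"`, `spark_min_area_px = 4`;
#' * `stats`: `var_equal = FALSE` (Welch t-test);
#' * `io`: `channel = "green"`, `fps_override = NULL`.
#'
#' @param file optional path to a JSON config file with any subset of
#'   the sections above.
#' @param overrides optional named list merged on top of file + defaults.
#' @return nested list of class `cf_config`.
#' @export
cf_config <- function(file = NULL, overrides = NULL) {
  cfg <- list(
    flow = list(alpha = 0.1, iterations = 400, tolerance = 1e-4,
                fraction = 1 / 3000, reduce = "mean"),
    peaks = list(min_rel_amplitude = 0.05, baseline_percentile = 10,
                 endpoint_frac = 0.20, max_gap_s = 0.1),
    calcium = list(spark_threshold = 10, width_height_frac = 0.10,
                   baseline_percentile = 10, background = "temporal_min",
                   normalize = "none", spark_min_area_px = 4),
    stats = list(var_equal = FALSE),
    io = list(channel = "green", fps_override = NULL)
  )
  if (!is.null(file)) {
    user <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "cf_config")
}

summary_to_list <- function(s) {
  out <- unclass(s)[setdiff(names(unclass(s)), "metrics")]
  if (nrow(s$metrics) > 0L) {
    out <- c(out,
             as.list(stats::setNames(s$metrics$mean, s$metrics$metric)),
             as.list(stats::setNames(s$metrics$sem,
                                     paste0(s$metrics$metric, "_sem"))))
  }
  out
}

#' Run the full analysis pipeline on a recording
#'
#' `mode = "contraction"`: optical-flow velocity trace, peak detection,
#' contraction/relaxation event pairing and kinetics summary.
#' `mode = "calcium"`: background subtraction, intensity trace, spark
#' series, transient kinetics and summary.
#'
#' When `out_dir` is given, writes `trace.csv`, `events.csv` (or
#' `transients.csv` + `sparks.csv`), `summary.json` and `config.json`
#' (the resolved configuration).  A directory input is analysed file by
#' file into subdirectories; a file that fails (unreadable, mixed frame
#' sizes ...) is reported as a warning and the run continues.
#'
#' @param input path to a video file or directory, or a [video_stack()].
#' @param mode `"contraction"` or `"calcium"`.
#' @param config a [cf_config()].
#' @param out_dir optional output directory.
#' @return For a single recording: list of class `cf_result` with the
#'   trace, events/transients table and summary.  For a directory: a
#'   list of `cf_result`/error entries, one per video file.
#' @export
analyze <- function(input, mode = c("contraction", "calcium"),
                    config = cf_config(), out_dir = NULL) {
  mode <- match.arg(mode)

  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(tif|tiff|avi)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no video files in ", input, call. = FALSE)
    out <- lapply(files, function(f) {
      sub <- if (is.null(out_dir)) NULL else
        file.path(out_dir, tools::file_path_sans_ext(basename(f)))
      tryCatch(analyze(f, mode, config, sub), error = function(e) {
        warning("skipping ", basename(f), ": ", conditionMessage(e), call. = FALSE)
        structure(list(file = f, error = conditionMessage(e)), class = "cf_error")
      })
    })
    names(out) <- basename(files)
    return(out)
  }

  stack <- if (inherits(input, "video_stack")) input else
    load_video(input, channel = config$io$channel,
               fps_override = config$io$fps_override)
  duration_s <- n_frames(stack) / stack$fps

  if (mode == "contraction") {
    trace <- velocity_trace(stack, alpha = config$flow$alpha,
                            n_iter = config$flow$iterations,
                            tol = config$flow$tolerance,
                            fraction = config$flow$fraction,
                            reduce = config$flow$reduce)
    bl <- trace_baseline(trace, config$peaks$baseline_percentile)
    peaks <- detect_peaks(trace, baseline = bl,
                          min_rel_amplitude = config$peaks$min_rel_amplitude,
                          endpoint_frac = config$peaks$endpoint_frac)
    paired <- pair_events(trace, peaks, max_gap_s = config$peaks$max_gap_s)
    summ <- summarize_kinetics(paired$events, duration_s)
    res <- structure(list(mode = mode, trace = trace, baseline = bl,
                          peaks = peaks, events = paired$events,
                          unmatched = paired$unmatched, summary = summ),
                     class = "cf_result")
  } else {
    bg <- subtract_background(stack,
      method = if (startsWith(config$calcium$background, "percentile"))
        "percentile" else "temporal_min")
    trace <- intensity_trace(bg, normalize = config$calcium$normalize,
                             baseline_percentile = config$calcium$baseline_percentile)
    sparks <- spark_series(bg, threshold = config$calcium$spark_threshold)
    transients <- transient_metrics(trace, sparks,
      baseline_percentile = config$calcium$baseline_percentile,
      width_height_frac = config$calcium$width_height_frac,
      min_rel_amplitude = config$peaks$min_rel_amplitude,
      spark_min_area_px = config$calcium$spark_min_area_px)
    summ <- summarize_transients(transients, duration_s)
    res <- structure(list(mode = mode, trace = trace, sparks = sparks,
                          transients = transients, summary = summ),
                     class = "cf_result")
  }

  if (!is.null(out_dir)) write_result(res, out_dir, config)
  res
}

#' @export
print.cf_result <- function(x, ...) {
  cat(sprintf("<cf_result> mode=%s\n", x$mode))
  print(x$summary)
  invisible(x)
}

events_to_csv <- function(events, dt) {
  data.frame(start_s = (events$c_start - 1) * dt,
             apex_s = (events$c_apex - 1) * dt,
             end_s = (events$r_end - 1) * dt,
             ttp_s = events$ttp_s,
             dfdt_max = events$dfdt_max,
             contraction_time_s = events$contraction_time_s,
             delay_s = events$delay_s,
             relaxation_time_s = events$relaxation_time_s)
}

write_result <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (res$mode == "contraction") {
    write_trace_csv(res$trace, file.path(out_dir, "trace.csv"),
                    value_name = "velocity_px_per_s")
    write.csv(events_to_csv(res$events, res$trace$dt),
              file.path(out_dir, "events.csv"), row.names = FALSE)
  } else {
    write_trace_csv(res$trace, file.path(out_dir, "trace.csv"),
                    value_name = "intensity")
    write.csv(res$transients, file.path(out_dir, "transients.csv"),
              row.names = FALSE)
    write.csv(data.frame(time_s = (seq_along(res$sparks$sp_intensity) - 0.5) *
                           res$sparks$dt,
                         sp_intensity = res$sparks$sp_intensity,
                         sp_area = res$sparks$sp_area),
              file.path(out_dir, "sparks.csv"), row.names = FALSE)
  }
  jsonlite::write_json(summary_to_list(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' Compare a treated group against control, normalized to control = 100%
#'
#' The statistical unit is the recording: each group is a vector of
#' per-recording metric means (one number per independent video), which
#' avoids pseudoreplication across beats.  The treated mean is expressed
#' as a percentage of the control mean (control = 100%), and a
#' two-tailed two-sample t-test (Welch by default) gives the p-value;
#' `p <= 0.05` is flagged significant.
#'
#' @param control,treated numeric vectors of per-recording means
#'   (length >= 2 each).
#' @param metric metric name, for labelling.
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for the pooled
#'   t-test.
#' @return list of class `group_comparison`: `metric`, `control_mean`,
#'   `control_sem`, `control_n`, `treated_mean`, `treated_sem`,
#'   `treated_n`, `normalized_pct`, `p_value`, `significant`.
#' @export
compare_groups <- function(control, treated, metric = "metric",
                           var_equal = FALSE) {
  control <- as.numeric(control); treated <- as.numeric(treated)
  if (length(control) < 2L || length(treated) < 2L)
    stop("each group needs >= 2 recordings", call. = FALSE)
  if (mean(control) == 0)
    stop("control mean is zero: normalization to control undefined", call. = FALSE)
  # t.test() refuses constant data; use the limiting p-value there
  p <- tryCatch(
    t.test(treated, control, var.equal = var_equal,
           alternative = "two.sided")$p.value,
    error = function(e) if (isTRUE(all.equal(mean(control), mean(treated))))
      1 else 0)
  structure(list(
    metric = metric,
    control_mean = mean(control), control_sem = sem(control),
    control_n = length(control),
    treated_mean = mean(treated), treated_sem = sem(treated),
    treated_n = length(treated),
    normalized_pct = 100 * mean(treated) / mean(control),
    p_value = unname(p),
    significant = unname(p) <= 0.05
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: control %.4g +/- %.3g (n=%d), treated %.4g +/- %.3g (n=%d)\n  treated = %.1f%% of control, p = %.3g%s\n",
    x$metric, x$control_mean, x$control_sem, x$control_n,
    x$treated_mean, x$treated_sem, x$treated_n,
    x$normalized_pct, x$p_value, if (x$significant) " (*)" else ""))
  invisible(x)
}

#' One-way ANOVA across more than two groups
#'
#' @param groups named list of numeric vectors (per-recording means), one
#'   per condition.
#' @return list with `p_value` and the per-group means, SEMs and
#'   normalized percentages (first group taken as control = 100%).
#' @export
groups_anova <- function(groups) {
  if (length(groups) < 3L)
    stop("use compare_groups() for two groups", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  ctrl <- mean(groups[[1]])
  list(p_value = p,
       means = vapply(groups, mean, numeric(1)),
       sems = vapply(groups, sem, numeric(1)),
       normalized_pct = vapply(groups, function(g) 100 * mean(g) / ctrl, numeric(1)))
}

#' Plot a trace with detected peaks
#'
#' Base-graphics overview plot: the trace, its baseline, and detected
#' peak apexes/endpoints.
#'
#' @param trace a [time_series()].
#' @param peaks optional `peak_table` from [detect_peaks()].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_trace <- function(trace, peaks = NULL, main = "", ...) {
  tt <- trace_times(trace)
  graphics::plot(tt, trace$values, type = "l", xlab = "time (s)",
                 ylab = "value", main = main, ...)
  if (!is.null(peaks) && nrow(peaks)) {
    graphics::abline(h = peaks$baseline[1], lty = 2, col = "grey50")
    graphics::points(tt[peaks$apex], trace$values[peaks$apex], col = "red", pch = 19)
    graphics::points(tt[peaks$start], trace$values[peaks$start], col = "blue", pch = 4)
    graphics::points(tt[peaks$end], trace$values[peaks$end], col = "blue", pch = 4)
  }
  invisible(NULL)
}
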