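# Synthetic cardiomyocyte videos with exact ground truth.
#
# Two stated worlds are emulated at the paper-scale defaults (50 fps,
# 10-30 s recordings):
#  * "contraction": a striped sarcomere-like (Z-disc) texture whose
#    horizontal displacement follows a smooth periodic
#    contraction-relaxation waveform (fast shortening, brief hold,
#    slower re-lengthening);
#  * "calcium": a static cell-shaped mask whose brightness follows a
#    double-exponential transient train, with optional brief bright
#    discs (sparks) at scheduled times.
#
# Ground truth is computed numerically from the closed-form waveforms
# (optimize/uniroot on the continuous signal), never by running the
# analysis code under test.

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Manifest for a synthetic video
#'
#' Records every parameter needed to regenerate a synthetic recording
#' bit-identically (including the RNG seed) plus, after generation, the
#' derived ground truth.
#'
#' @param kind `"contraction"` or `"calcium"`.
#' @param fps frame rate (default 50, the recording rate the analysis
#'   targets).
#' @param duration_s recording length in seconds.
#' @param width,height frame size in pixels.
#' @param noise_sd additive Gaussian pixel noise, 8-bit units.  The
#'   default of 2 is a realistic camera noise floor; it also keeps the
#'   zero-pixel-exclusion rule of [intensity_trace()] in its intended
#'   regime (in a perfectly noiseless video the background-subtracted
#'   diastolic cell is exactly zero, so the zero-excluded mean would be
#'   dominated by any isolated bright spot).  Pass 0 for the noiseless
#'   oracle world used in timing tests.
#' @param seed RNG seed.
#' @param ... kind-specific parameters, see
#'   [make_contraction_video()] / [make_calcium_video()].
#' @return list of class `synth_manifest`.
#' @export
synth_manifest <- function(kind = c("contraction", "calcium"), fps = 50,
                           duration_s = 10, width = 128, height = 128,
                           noise_sd = 2, seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- if (kind == "contraction") {
    list(period_s = 1.0, phase_s = 0.1, displacement_px = 6,
         stripe_period_px = 12, t_contract_s = 0.15, t_hold_s = 0.06,
         t_relax_s = 0.25, offset = 127, contrast = 100)
  } else {
    list(period_s = 1.0, t_first_s = 0.25, amplitude = 120, base = 10,
         tau_rise_s = 0.03, tau_decay_s = 0.17,
         spark_times = numeric(0), spark_mag = 60, spark_radius = 2,
         spark_frames = 2, spark_positions = NULL)
  }
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- c(list(kind = kind, fps = fps, duration_s = duration_s,
              width = width, height = height, noise_sd = noise_sd,
              seed = seed),
         modifyList(defaults, extra))
  structure(m, class = "synth_manifest")
}

#' @export
print.synth_manifest <- function(x, ...) {
  cat(sprintf("<synth_manifest> kind=%s, %g s @ %g fps, %dx%d px, noise_sd=%g, seed=%d\n",
              x$kind, x$duration_s, x$fps, x$width, x$height, x$noise_sd, x$seed))
  invisible(x)
}

# Periodic contraction-relaxation displacement waveform in [0, 1]:
# raised-cosine rise over t_contract, hold, raised-cosine fall over
# t_relax, rest until the next beat.
contraction_waveform <- function(t, period, phase, tc, th, tr) {
  s <- t - phase
  lo <- s - floor(s / period) * period
  w <- numeric(length(t))
  w[s >= 0 & lo < tc] <- 0.5 * (1 - cos(pi * lo[s >= 0 & lo < tc] / tc))
  w[s >= 0 & lo >= tc & lo < tc + th] <- 1
  fall <- s >= 0 & lo >= tc + th & lo < tc + th + tr
  w[fall] <- 0.5 * (1 + cos(pi * (lo[fall] - tc - th) / tr))
  w
}

#' Generate a synthetic contraction video
#'
#' Renders a sinusoidal vertical stripe texture (stripe period >= 8 px,
#' band-limited so the flow estimator stays in its small-motion regime)
#' whose horizontal displacement is `d(t) = A * w(t)` with `w` the
#' periodic contraction-relaxation waveform.  Ground truth recorded in
#' the manifest: per-frame displacement, per-frame-pair speed
#' (`|diff(d)| * fps`), the number of complete beats and the true beat
#' rate, and the analytic peak contraction/relaxation speeds.
#'
#' Generation refuses (aliasing error) when the per-frame displacement
#' exceeds half the stripe period, where the pattern motion becomes
#' ambiguous.
#'
#' @param manifest a [synth_manifest()] with `kind = "contraction"`.
#'   Parameters: `period_s`, `phase_s` (start of the first beat),
#'   `displacement_px` (A), `stripe_period_px`, `t_contract_s`,
#'   `t_hold_s`, `t_relax_s`, `offset`, `contrast`, `noise_sd`, `seed`.
#' @return list with `stack` (a [video_stack()]) and `manifest` with a
#'   `truth` element filled in.
#' @export
make_contraction_video <- function(manifest) {
  stopifnot(inherits(manifest, "synth_manifest"))
  if (manifest$kind != "contraction")
    stop("manifest kind must be 'contraction'", call. = FALSE)
  m <- manifest
  if (m$stripe_period_px < 8)
    stop("stripe period must be >= 8 px (band-limited texture)", call. = FALSE)
  n <- round(m$duration_s * m$fps)
  tt <- (seq_len(n) - 1) / m$fps
  d <- m$displacement_px *
    contraction_waveform(tt, m$period_s, m$phase_s,
                         m$t_contract_s, m$t_hold_s, m$t_relax_s)
  if (max(abs(diff(d))) > m$stripe_period_px / 2)
    stop("aliasing: per-frame displacement exceeds half the stripe period; ",
         "reduce displacement or speed, or widen the stripes", call. = FALSE)

  x <- seq_len(m$width)
  frames <- array(0, c(m$height, m$width, n))
  for (k in seq_len(n)) {
    row <- m$offset + m$contrast * sin(2 * pi * (x - d[k]) / m$stripe_period_px)
    frames[, , k] <- matrix(row, nrow = m$height, ncol = m$width, byrow = TRUE)
  }
  if (m$noise_sd > 0) {
    frames <- frames + with_seed(m$seed, array(rnorm(length(frames), 0, m$noise_sd),
                                               dim(frames)))
  }
  frames <- round(pmin(pmax(frames, 0), 255))

  beat_len <- m$t_contract_s + m$t_hold_s + m$t_relax_s
  n_beats <- if (m$duration_s >= m$phase_s + beat_len)
    floor((m$duration_s - m$phase_s - beat_len) / m$period_s) + 1 else 0
  m$truth <- list(
    displacement_px = d,
    speed_px_s = abs(diff(d)) * m$fps,
    peak_speed_px_s = max(abs(diff(d))) * m$fps,
    peak_contraction_speed_px_s = m$displacement_px * pi / (2 * m$t_contract_s),
    peak_relaxation_speed_px_s = m$displacement_px * pi / (2 * m$t_relax_s),
    n_beats = n_beats,
    beat_rate_hz = n_beats / m$duration_s)
  list(stack = video_stack(frames, fps = m$fps, channel = "gray"), manifest = m)
}

# Double-exponential calcium transient train, unit amplitude scale.
calcium_waveform <- function(t, onsets, tau_rise, tau_decay) {
  g <- numeric(length(t))
  for (tk in onsets) {
    s <- t - tk
    on <- s >= 0
    g[on] <- g[on] + (1 - exp(-s[on] / tau_rise)) * exp(-s[on] / tau_decay)
  }
  g
}

# Onset schedule: all transient starts inside the recording.
calcium_onsets <- function(m) {
  if (m$duration_s < m$t_first_s) return(numeric(0))
  k <- floor((m$duration_s - m$t_first_s) / m$period_s) + 1
  m$t_first_s + (seq_len(k) - 1) * m$period_s
}

# Ground-truth kinetics from the continuous waveform: baseline from a
# finely sampled series (same percentile convention as the analysis),
# crossings by bisection (uniroot), peaks by golden-section (optimize).
calcium_truth <- function(m) {
  onsets <- calcium_onsets(m)
  if (length(onsets) == 0L) {
    return(list(transients = data.frame(), baseline = 0, dfdt_max = 0,
                n_transients = 0L, rate_hz = 0))
  }
  g <- function(t) calcium_waveform(t, onsets, m$tau_rise_s, m$tau_decay_s)
  fine <- seq(0, m$duration_s, by = 1 / 5000)
  bl <- quantile(g(fine), 0.10, type = 7, names = FALSE)

  per <- lapply(seq_along(onsets), function(k) {
    tk <- onsets[k]
    wend <- min(tk + m$period_s, m$duration_s)
    op <- optimize(g, c(tk, wend), maximum = TRUE, tol = 1e-7)
    pk_t <- op$maximum; pk_v <- op$objective
    amp <- pk_v - bl
    lev <- bl + 0.10 * amp
    t0 <- if (g(tk) < lev) uniroot(function(t) g(t) - lev, c(tk, pk_t),
                                   tol = 1e-7)$root else tk
    t90 <- NA_real_; tcross <- NA_real_
    if (g(wend) < lev) {
      tcross <- uniroot(function(t) g(t) - lev, c(pk_t, wend), tol = 1e-7)$root
      t90 <- tcross - pk_t
    }
    data.frame(onset_s = tk, t0_s = t0, peak_s = pk_t, ttp_s = pk_t - t0,
               t90_s = t90, width10_s = if (is.na(tcross)) NA_real_ else tcross - t0,
               amplitude = m$amplitude * amp)
  })
  truth <- do.call(rbind, per)

  # frame-sampled maximal upstroke slope (what (dF/dT)max measures)
  tfr <- (seq_len(round(m$duration_s * m$fps)) - 1) / m$fps
  gf <- m$amplitude * g(tfr)
  dfdt <- max(diff(gf)) * m$fps

  # scheduled sparks falling strictly before each transient's t0 and
  # after the previous transient's 10%-decay crossing
  spark_counts <- vapply(seq_along(onsets), function(k) {
    lo <- if (k > 1) truth$t0_s[k - 1] + truth$width10_s[k - 1] else 0
    if (is.na(lo)) lo <- onsets[k - 1]
    sum(m$spark_times > lo & m$spark_times < truth$t0_s[k])
  }, numeric(1))
  truth$spark_count_before <- spark_counts

  list(transients = truth, baseline = m$amplitude * bl,
       dfdt_max = dfdt, n_transients = length(onsets),
       rate_hz = length(onsets) / m$duration_s)
}

#' Generate a synthetic calcium video
#'
#' Renders an elliptical cell mask on a dark background; cell brightness
#' follows `base + amplitude * sum_k (1 - exp(-(t - tk)/tau_rise)) *
#' exp(-(t - tk)/tau_decay)`, the standard cardiac calcium transient
#' family, with onsets every `period_s` starting at `t_first_s`, scaled
#' per pixel by a static random indicator-expression profile (uniform in
#' 0.6--1.4, seeded).
#' Optional sparks are brief (`spark_frames` frames) bright discs of
#' radius `spark_radius` at `spark_times`, placed at `spark_positions`
#' (or at seeded random positions inside the cell).
#'
#' The manifest ground truth (`t0`, TTP, T90, width at 10% height,
#' amplitude, frame-sampled maximal upstroke slope, spark counts) is
#' computed numerically from the noiseless closed-form waveform by
#' golden-section/bisection -- independent of the analysis code.  Onsets
#' closer together than `tau_decay_s` set a `truncated` warning flag in
#' the manifest (transients overlap strongly).
#'
#' @param manifest a [synth_manifest()] with `kind = "calcium"`.
#' @return list with `stack` (a [video_stack()], green channel) and
#'   `manifest` with `truth` filled in.
#' @export
make_calcium_video <- function(manifest) {
  stopifnot(inherits(manifest, "synth_manifest"))
  if (manifest$kind != "calcium")
    stop("manifest kind must be 'calcium'", call. = FALSE)
  m <- manifest
  onsets <- calcium_onsets(m)
  m$overlap_warning <- length(onsets) > 1 && min(diff(onsets)) < m$tau_decay_s
  if (m$overlap_warning)
    warning("transient onsets closer than tau_decay: strong overlap", call. = FALSE)

  n <- round(m$duration_s * m$fps)
  tt <- (seq_len(n) - 1) / m$fps
  w <- calcium_waveform(tt, onsets, m$tau_rise_s, m$tau_decay_s)

  cy <- (m$height + 1) / 2; cx <- (m$width + 1) / 2
  ry <- 0.30 * m$height; rx <- 0.35 * m$width
  yy <- matrix(seq_len(m$height), m$height, m$width)
  xx <- matrix(seq_len(m$width), m$height, m$width, byrow = TRUE)
  cell <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1

  # static per-pixel indicator-expression profile: real cells are not
  # uniformly bright, and a flat cell is degenerate under 8-bit
  # quantization (the whole mask crosses integer levels in lockstep)
  expr <- with_seed(m$seed + 2L,
                    matrix(runif(m$height * m$width, 0.6, 1.4),
                           m$height, m$width))

  # seeded spark positions inside the cell, drawn before pixel noise so
  # the same seed always yields the same geometry
  n_sp <- length(m$spark_times)
  if (n_sp > 0 && is.null(m$spark_positions)) {
    inside <- which(cell, arr.ind = TRUE)
    m$spark_positions <- with_seed(m$seed + 1L,
      inside[sample(nrow(inside), n_sp, replace = TRUE), , drop = FALSE])
  }

  frames <- array(0, c(m$height, m$width, n))
  for (k in seq_len(n)) {
    f <- matrix(0, m$height, m$width)
    f[cell] <- expr[cell] * (m$base + m$amplitude * w[k])
    frames[, , k] <- f
  }
  if (n_sp > 0) {
    for (s in seq_len(n_sp)) {
      f0 <- round(m$spark_times[s] * m$fps) + 1L
      pos <- m$spark_positions[s, ]
      disc <- (yy - pos[1])^2 + (xx - pos[2])^2 <= m$spark_radius^2
      for (k in f0:min(f0 + m$spark_frames - 1L, n)) {
        if (k >= 1L) frames[, , k][disc] <- frames[, , k][disc] + m$spark_mag
      }
    }
  }
  if (m$noise_sd > 0) {
    frames <- frames + with_seed(m$seed, array(rnorm(length(frames), 0, m$noise_sd),
                                               dim(frames)))
  }
  frames <- round(pmin(pmax(frames, 0), 255))

  m$truth <- calcium_truth(m)
  list(stack = video_stack(frames, fps = m$fps, channel = "green"), manifest = m)
}

#' Generate a matched control/treated pair of synthetic recording groups
#'
#' Emulates a drug-versus-control experiment: `n` control and `n`
#' treated calcium recordings that differ only by the stated
#' multiplicative factors (and by their seeds).  `amplitude` scales the
#' transient amplitude (and thus the maximal upstroke slope, the
#' inotropy readout), `tau_decay` scales the decay constant (the T90 /
#' lusitropy readout) and `beat_rate` divides the beat period (the
#' chronotropy readout).
#'
#' The expected percentage effects are computed from the noiseless
#' closed-form oracle of each group, not from the analysis pipeline.
#'
#' @param control a [synth_manifest()] with `kind = "calcium"` serving as
#'   the control condition.
#' @param effect named list of factors: `amplitude`, `tau_decay`,
#'   `beat_rate` (each default 1).
#' @param n recordings per group (>= 2; SEM is undefined below that).
#' @return list with `control` and `treated` (each a list of
#'   `list(stack, manifest)`) and `expected`: `dfdt_pct`, `t90_pct`
#'   (treated as percent of control) and `beat_rate_ratio`.
#' @export
make_group_pair <- function(control, effect = list(), n = 6) {
  stopifnot(inherits(control, "synth_manifest"))
  if (control$kind != "calcium")
    stop("group pairs are generated from calcium manifests", call. = FALSE)
  if (n < 2) stop("n must be >= 2 (SEM undefined for n < 2)", call. = FALSE)
  eff <- modifyList(list(amplitude = 1, tau_decay = 1, beat_rate = 1), effect)

  treated <- control
  treated$amplitude <- control$amplitude * eff$amplitude
  treated$tau_decay_s <- control$tau_decay_s * eff$tau_decay
  treated$period_s <- control$period_s / eff$beat_rate

  gen <- function(base, seed_off) {
    lapply(seq_len(n), function(i) {
      mi <- base
      mi$seed <- base$seed + seed_off + i
      make_calcium_video(mi)
    })
  }
  ctrl_vids <- gen(control, 0L)
  trt_vids <- gen(treated, 100L)

  tr_c <- calcium_truth(control)
  tr_t <- calcium_truth(treated)
  expected <- list(
    dfdt_pct = 100 * tr_t$dfdt_max / tr_c$dfdt_max,
    t90_pct = 100 * mean(tr_t$transients$t90_s, na.rm = TRUE) /
      mean(tr_c$transients$t90_s, na.rm = TRUE),
    beat_rate_ratio = tr_t$n_transients / tr_c$n_transients)

  list(control = ctrl_vids, treated = trt_vids, expected = expected)
}
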