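test_that("baseline is the linear-interpolation percentile", {
  expect_equal(trace_baseline(rep(7, 20)), 7)
  expect_equal(trace_baseline(0:100, percentile = 10), 10)
  expect_equal(trace_baseline(c(rep(0, 9), 100), percentile = 10), 0)
  expect_equal(trace_baseline(time_series(0:100, 0.02), 50), 50)
  expect_error(trace_baseline(1:5, percentile = 101), "percentile")
})

test_that("flat and monotone traces yield no peaks", {
  expect_equal(nrow(detect_peaks(rep(3, 50), baseline = 0)), 0)
  expect_equal(nrow(detect_peaks(1:50, baseline = 0)), 0)
})

test_that("the 5% relative amplitude rule filters small bumps", {
  # triangle to 100 plus a bump of 4: 4 < 5% of 100, dropped
  v <- c(rep(0, 3), seq(0, 100, by = 20), seq(80, 0, by = -20),
         rep(0, 3), 0, 4, 0, rep(0, 3))
  pk <- detect_peaks(v, baseline = 0)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, 100)
  # a bump of 6 >= 5 survives
  v2 <- replace(v, which(v == 4), 6)
  expect_equal(nrow(detect_peaks(v2, baseline = 0)), 2)
})

test_that("endpoints sit at the 20% crossings of a triangular peak", {
  # rise 0 -> 100 over samples 0..10, fall back over 10..20 (0-based)
  v <- c(seq(0, 100, by = 10), seq(90, 0, by = -10))
  pk <- detect_peaks(v, baseline = 0, endpoint_frac = 0.2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex, 11)    # 0-based sample 10
  expect_equal(pk$start, 3)    # 0-based sample 2, value 20
  expect_equal(pk$end, 19)     # 0-based sample 18, value 20
  expect_false(pk$truncated_left || pk$truncated_right)
})

test_that("plateaus take their centre sample, left-centre when even", {
  v <- c(0, 1, 1, 0)
  expect_equal(detect_peaks(v, baseline = 0)$apex, 2)
  v <- c(0, 1, 1, 1, 0)
  expect_equal(detect_peaks(v, baseline = 0)$apex, 3)
})

test_that("boundary-truncated peaks are flagged", {
  v <- c(seq(0, 100, by = 20), seq(95, 60, by = -5))  # never falls to 20
  pk <- detect_peaks(v, baseline = 0, endpoint_frac = 0.2)
  expect_equal(nrow(pk), 1)
  expect_true(pk$truncated_right)
  expect_equal(pk$end, length(v))
})

test_that("pairing is greedy with the max-gap rule", {
  tri <- function(amp) c(seq(0, amp, length.out = 6), seq(amp, 0, length.out = 6)[-1])
  dt <- 0.02
  # single peak: no events, one unmatched
  v1 <- c(rep(0, 3), tri(100), rep(0, 3))
  p1 <- pair_events(time_series(v1, dt), detect_peaks(v1, baseline = 0))
  expect_equal(nrow(p1$events), 0)
  expect_equal(p1$unmatched, 1)

  # two peaks, gap 1 sample = 0.02 s <= 0.1 -> one event
  v2 <- c(rep(0, 3), tri(100), 0, tri(80), rep(0, 3))
  pk2 <- detect_peaks(v2, baseline = 0)
  p2 <- pair_events(time_series(v2, dt), pk2)
  expect_equal(nrow(p2$events), 1)
  expect_equal(p2$events$delay_s, (pk2$start[2] - pk2$end[1]) * dt)
  expect_length(p2$unmatched, 0)

  # three peaks, gaps ~0.02 s and ~0.5 s -> peaks 1-2 paired, 3 unmatched
  v3 <- c(rep(0, 3), tri(100), 0, tri(80), rep(0, 25), tri(90), rep(0, 3))
  pk3 <- detect_peaks(v3, baseline = 0)
  expect_equal(nrow(pk3), 3)
  p3 <- pair_events(time_series(v3, dt), pk3)
  expect_equal(nrow(p3$events), 1)
  expect_equal(p3$unmatched, 3)
})

test_that("event metrics follow their definitions on a hand-built trace", {
  dt <- 0.02
  v <- c(0, 0, 10, 40, 100, 60, 20, 0, 0, 20, 70, 90, 50, 20, 0, 0)
  pk <- detect_peaks(v, baseline = 0, endpoint_frac = 0.2)
  p <- pair_events(time_series(v, dt), pk)
  expect_equal(nrow(p$events), 1)
  ev <- p$events
  expect_equal(ev$ttp_s, (pk$apex[1] - pk$start[1]) * dt)
  expect_equal(ev$contraction_time_s, (pk$end[1] - pk$start[1]) * dt)
  expect_equal(ev$relaxation_time_s, (pk$end[2] - pk$start[2]) * dt)
  # steepest rise on the contraction upstroke is 40 -> 100
  expect_equal(ev$dfdt_max, 60 / dt)
})

test_that("kinetics are invariant to trace shift and equivariant to scale", {
  set.seed(11)
  for (rep in 1:20) {
    v <- random_pl_trace(300)
    pk <- detect_peaks(v)
    p <- pair_events(v, pk, dt = 0.02)
    # shift: identical indices and timings, dfdt unchanged
    pk_s <- detect_peaks(v + 37)
    p_s <- pair_events(v + 37, pk_s, dt = 0.02)
    expect_equal(pk_s[c("start", "apex", "end")], pk[c("start", "apex", "end")])
    expect_equal(p_s$events$dfdt_max, p$events$dfdt_max)
    # scale: timings identical, amplitudes and dfdt scaled
    pk_c <- detect_peaks(v * 3.5)
    p_c <- pair_events(v * 3.5, pk_c, dt = 0.02)
    expect_equal(pk_c[c("start", "apex", "end")], pk[c("start", "apex", "end")])
    expect_equal(pk_c$amplitude, pk$amplitude * 3.5, tolerance = 1e-9)
    expect_equal(p_c$events$dfdt_max, p$events$dfdt_max * 3.5, tolerance = 1e-9)
  }
})

test_that("detect_peaks + pair_events match the literal rule oracle", {
  set.seed(12)
  for (rep in 1:200) {
    v <- random_pl_trace(sample(50:400, 1))
    bl <- trace_baseline(v)
    pk <- detect_peaks(v, baseline = bl)
    ora <- oracle_peaks(v, bl)
    expect_equal(pk$start, ora$start)
    expect_equal(pk$apex, ora$apex)
    expect_equal(pk$end, ora$end)
    pairs <- oracle_pair(ora, 0.1, 0.02)
    p <- pair_events(v, pk, max_gap_s = 0.1, dt = 0.02)
    expect_equal(nrow(p$events), if (is.null(pairs)) 0L else nrow(pairs))
    if (!is.null(pairs)) {
      expect_equal(p$events$c_apex, ora$apex[pairs[, 1]])
      expect_equal(p$events$r_apex, ora$apex[pairs[, 2]])
    }
  }
})

test_that("summaries report rate and mean +/- SEM correctly", {
  ev <- data.frame(ttp_s = c(0.1, 0.2, 0.3), dfdt_max = c(1, 1, 1),
                   contraction_time_s = c(0.2, 0.2, 0.2),
                   relaxation_time_s = c(0.3, 0.3, 0.3),
                   delay_s = c(0, 0, 0))
  s <- summarize_kinetics(ev[rep(1, 4), ], duration_s = 2)
  expect_equal(s$beat_rate_hz, 2.0)
  s3 <- summarize_kinetics(ev, duration_s = 3)
  expect_equal(s3$metrics$mean[s3$metrics$metric == "ttp_s"], 0.2)
  expect_equal(s3$metrics$sem[s3$metrics$metric == "ttp_s"],
               sd(c(0.1, 0.2, 0.3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(s3$metrics$sem[s3$metrics$metric == "ttp_s"], 0.0577,
               tolerance = 1e-3)
  # identical values: SEM exactly 0; single event: SEM absent (NA)
  s2 <- summarize_kinetics(ev[c(1, 1), ], duration_s = 1)
  expect_equal(s2$metrics$sem[1], 0)
  s1 <- summarize_kinetics(ev[1, ], duration_s = 1)
  expect_true(all(is.na(s1$metrics$sem)))
  # empty events
  s0 <- summarize_kinetics(ev[0, ], duration_s = 5)
  expect_equal(s0$n_events, 0)
  expect_equal(s0$beat_rate_hz, 0)
})

test_that("beat rate is exact on a synthetic periodic velocity trace", {
  g <- make_contraction_video(synth_manifest("contraction", duration_s = 4,
                                             width = 48, height = 48, seed = 13,
                                             noise_sd = 0))
  vt <- velocity_trace(g$stack, alpha = 0.05, n_iter = 400, tol = 1e-5)
  pk <- detect_peaks(vt, baseline = trace_baseline(vt))
  p <- pair_events(vt, pk)
  s <- summarize_kinetics(p$events, duration_s = 4)
  expect_equal(s$n_events, g$manifest$truth$n_beats)
  expect_equal(s$beat_rate_hz, g$manifest$truth$beat_rate_hz)
})
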