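test_that("generation is bit-identical for a fixed seed", {
  m <- synth_manifest("contraction", duration_s = 1, width = 32, height = 32,
                      seed = 5, noise_sd = 2)
  expect_identical(make_contraction_video(m)$stack$frames,
                   make_contraction_video(m)$stack$frames)

  mc <- synth_manifest("calcium", duration_s = 1, width = 32, height = 32,
                       seed = 5, spark_times = 0.1)
  g1 <- make_calcium_video(mc); g2 <- make_calcium_video(mc)
  expect_identical(g1$stack$frames, g2$stack$frames)
  expect_identical(g1$manifest$spark_positions, g2$manifest$spark_positions)

  # different seeds differ (noise is actually applied)
  mc2 <- synth_manifest("calcium", duration_s = 1, width = 32, height = 32,
                        seed = 6, spark_times = 0.1)
  expect_false(identical(make_calcium_video(mc2)$stack$frames, g1$stack$frames))
})

test_that("zero displacement gives a static video and a zero velocity trace", {
  m <- synth_manifest("contraction", duration_s = 1, width = 32, height = 32,
                      displacement_px = 0, noise_sd = 0, seed = 1)
  g <- make_contraction_video(m)
  expect_equal(g$manifest$truth$peak_speed_px_s, 0)
  vt <- velocity_trace(g$stack, n_iter = 50)
  expect_true(all(vt$values == 0))
})

test_that("beat count and rate follow from the construction", {
  m <- synth_manifest("contraction", duration_s = 10, width = 16, height = 16,
                      period_s = 1.0, noise_sd = 0)
  g <- make_contraction_video(m)
  expect_equal(g$manifest$truth$n_beats, 10)
  expect_equal(g$manifest$truth$beat_rate_hz, 1.0)
  expect_equal(length(g$manifest$truth$speed_px_s), n_frames(g$stack) - 1)
})

test_that("aliasing displacement is refused", {
  m <- synth_manifest("contraction", duration_s = 1, width = 32, height = 32,
                      displacement_px = 40, stripe_period_px = 8,
                      t_contract_s = 0.05)
  expect_error(make_contraction_video(m), "aliasing")
})

test_that("manifest parameters are validated", {
  expect_error(synth_manifest("contraction", tau_rise_s = 1), "unknown parameter")
  m <- synth_manifest("calcium", width = 16, height = 16, duration_s = 0.5)
  expect_error(make_contraction_video(m), "kind")
})

test_that("calcium truth matches the closed-form waveform scale", {
  m <- synth_manifest("calcium", duration_s = 1.2, width = 32, height = 32,
                      noise_sd = 0)
  g <- make_calcium_video(m)
  tr <- g$manifest$truth
  expect_equal(tr$n_transients, 1)
  # double-exponential peak time: tau_r * log((tau_r + tau_d) / tau_r)
  tpk <- 0.03 * log((0.03 + 0.17) / 0.03)
  expect_equal(tr$transients$peak_s - tr$transients$onset_s, tpk, tolerance = 1e-5)
  # TTP ~ 0.05-0.06 s and T90 ~ 0.41-0.42 s for the default taus
  expect_lt(abs(tr$transients$ttp_s - 0.055), 0.005)
  expect_lt(abs(tr$transients$t90_s - 0.419), 0.005)
})

test_that("a recording too short for any transient yields zero transients", {
  # noiseless: with a pure-noise trace the *relative* 5% amplitude rule
  # has no absolute floor and would report noise bumps as transients
  m <- synth_manifest("calcium", duration_s = 0.2, width = 24, height = 24,
                      t_first_s = 0.5, noise_sd = 0)
  g <- expect_silent(make_calcium_video(m))
  expect_equal(g$manifest$truth$n_transients, 0)
  r <- analyze(g$stack, "calcium")
  expect_equal(nrow(r$transients), 0)
})

test_that("scheduled sparks appear in the truth and in the analysis", {
  m <- synth_manifest("calcium", duration_s = 1.2, width = 48, height = 48,
                      seed = 31, spark_times = c(0.06, 0.12, 0.18))
  g <- make_calcium_video(m)
  expect_equal(g$manifest$truth$transients$spark_count_before, 3)
  r <- analyze(g$stack, "calcium")
  expect_equal(nrow(r$transients), 1)
  expect_equal(r$transients$spark_count_before, 3)
})

test_that("overlapping transients set the manifest warning flag", {
  m <- synth_manifest("calcium", duration_s = 1, width = 16, height = 16,
                      period_s = 0.1, tau_decay_s = 0.17)
  expect_warning(g <- make_calcium_video(m), "overlap")
  expect_true(g$manifest$overlap_warning)
})

test_that("group pairs encode the stated effects in their expected values", {
  base <- synth_manifest("calcium", duration_s = 5, width = 24, height = 24,
                         seed = 40)
  gp0 <- make_group_pair(base, effect = list(), n = 2)
  expect_equal(gp0$expected$dfdt_pct, 100)
  expect_equal(gp0$expected$t90_pct, 100)
  expect_equal(gp0$expected$beat_rate_ratio, 1)

  gp <- make_group_pair(base, effect = list(amplitude = 1.5), n = 2)
  expect_equal(gp$expected$dfdt_pct, 150, tolerance = 1e-9)
  expect_length(gp$control, 2)
  expect_length(gp$treated, 2)
  # groups differ only by the stated factor: same geometry, same schedule
  expect_equal(gp$treated[[1]]$manifest$period_s, base$period_s)

  gp2 <- make_group_pair(base, effect = list(beat_rate = 2.2), n = 2)
  expect_equal(gp2$expected$beat_rate_ratio, 2.2)

  gp3 <- make_group_pair(base, effect = list(tau_decay = 1.2), n = 2)
  expect_gt(gp3$expected$t90_pct, 110)

  expect_error(make_group_pair(base, n = 1), "SEM")
})

test_that("noiseless end-to-end recovery hits the manifest truth", {
  m <- synth_manifest("contraction", duration_s = 3, width = 48, height = 48,
                      seed = 41, noise_sd = 0)
  g <- make_contraction_video(m)
  vt <- velocity_trace(g$stack, alpha = 0.05, n_iter = 600, tol = 1e-6)
  expect_lt(abs(max(vt$values) - g$manifest$truth$peak_speed_px_s) /
              g$manifest$truth$peak_speed_px_s, 0.25)
  pk <- detect_peaks(vt)
  p <- pair_events(vt, pk)
  expect_equal(nrow(p$events), g$manifest$truth$n_beats)
})
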