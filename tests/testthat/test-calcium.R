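test_that("temporal-minimum background subtraction is exact and idempotent", {
  # constant video -> all zero
  const <- video_stack(array(42, c(6, 6, 4)), fps = 50, channel = "green")
  expect_true(all(subtract_background(const)$frames == 0))

  # pixel time series [10, 30, 10] -> [0, 20, 0]
  fr <- array(10, c(4, 4, 3)); fr[2, 2, 2] <- 30
  st <- video_stack(fr, fps = 50, channel = "green")
  bg <- subtract_background(st)
  expect_equal(bg$frames[2, 2, ], c(0, 20, 0))
  expect_true(all(bg$frames[1, 1, ] == 0))

  # idempotence
  expect_equal(subtract_background(bg)$frames, bg$frames)
})

test_that("an additive constant offset is removed exactly", {
  g <- make_calcium_video(synth_manifest("calcium", duration_s = 1.2,
                                         width = 24, height = 24, seed = 20,
                                         noise_sd = 0))
  plain <- g$stack
  offset <- video_stack(pmin(plain$frames + 40, 255), fps = plain$fps,
                        channel = "green")
  # stay below clipping so the offset is truly additive
  expect_lt(max(plain$frames), 216)
  expect_equal(subtract_background(offset)$frames,
               subtract_background(plain)$frames)
})

test_that("intensity trace excludes zero pixels and normalizes on request", {
  f1 <- matrix(0, 10, 10); f1[1:5, ] <- 100      # half 100s, half 0s
  f2 <- matrix(0, 10, 10); f2[1:5, ] <- 50
  st <- stack_from_frames(f2, f1, channel = "green")
  tr <- intensity_trace(st, normalize = "none")
  expect_equal(tr$values, c(50, 100))
  trn <- intensity_trace(st, normalize = "max255")
  expect_equal(trn$values, c(127.5, 255))
  expect_false(attr(trn, "flagged"))

  zero <- video_stack(array(0, c(4, 4, 3)), fps = 50, channel = "green")
  trz <- intensity_trace(zero)
  expect_true(all(trz$values == 0))
  expect_true(attr(trz, "flagged"))
})

test_that("spark series thresholds frame differences at >= threshold", {
  a <- matrix(0, 20, 20)
  expect_equal(spark_series(stack_from_frames(a, a, channel = "green"))$sp_area, 0)

  # exactly 5% of pixels rise by 20
  b <- a; b[1, 1:20] <- 20
  sp <- spark_series(stack_from_frames(a, b, channel = "green"), threshold = 10)
  expect_equal(sp$sp_area, 0.05)
  expect_equal(sp$sp_intensity, 255)   # normalized series maximum

  # all diffs 9 < 10: nothing crosses (inclusive >= rule)
  c9 <- a + 9
  sp9 <- spark_series(stack_from_frames(a, c9, channel = "green"), threshold = 10)
  expect_equal(sp9$sp_area, 0)
  expect_true(sp9$flagged)
  # exactly 10 crosses
  c10 <- a + 10
  expect_equal(spark_series(stack_from_frames(a, c10, channel = "green"))$sp_area, 1)

  # intensity drops never count as sparks
  spd <- spark_series(stack_from_frames(b, a, channel = "green"))
  expect_equal(spd$sp_area, 0)
})

test_that("sp_intensity is zero wherever sp_area is zero", {
  g <- make_calcium_video(synth_manifest("calcium", duration_s = 2,
                                         width = 32, height = 32, seed = 21))
  sp <- spark_series(subtract_background(g$stack))
  expect_true(all(sp$sp_intensity[sp$sp_area == 0] == 0))
  expect_true(all(sp$sp_area >= 0 & sp$sp_area <= 1))
})

test_that("T90 of an exponential decay equals tau * ln(10) within a sample", {
  dt <- 0.02
  for (tau in c(0.1, 0.2, 0.4)) {
    decay <- 255 * exp(-seq(0, 6 * tau, by = dt) / tau)
    v <- c(rep(0, 150), decay, rep(0, 10))   # zeros pin the 10th-pct baseline at 0
    tm <- transient_metrics(time_series(v, dt))
    expect_equal(nrow(tm), 1)
    expect_lt(abs(tm$t90_s - tau * log(10)), dt + 1e-9,
              label = sprintf("tau = %g", tau))
  }
})

test_that("width at 10% height of a 1 s triangular pulse is 0.9 s", {
  dt <- 0.02
  up <- seq(0, 200, length.out = 26)           # 0.5 s rise
  v <- c(rep(0, 50), up, rev(up)[-1], rep(0, 50))
  tm <- transient_metrics(time_series(v, dt))
  expect_equal(nrow(tm), 1)
  expect_lt(abs(tm$width10_s - 0.9), dt + 1e-9)
})

test_that("spark peaks before a transient are counted in the right window", {
  dt <- 0.02
  v <- c(rep(0, 50), seq(0, 200, length.out = 6), seq(200, 0, length.out = 21),
         rep(0, 20))
  n <- length(v)
  sp_i <- numeric(n - 1); sp_a <- numeric(n - 1)
  sp_i[c(10, 30)] <- c(60, 55)                 # two isolated bumps before t0
  sp_a[c(10, 30)] <- 13 / 4096
  sparks <- structure(list(sp_intensity = sp_i, sp_area = sp_a,
                           n_pixels = 4096, dt = dt, threshold = 10,
                           flagged = FALSE), class = "spark_series")
  tm <- transient_metrics(time_series(v, dt), sparks)
  expect_equal(nrow(tm), 1)
  expect_equal(tm$spark_count_before, 2)

  # single-pixel noise bumps are rejected by the minimum-area rule
  sp_i[20] <- 50; sp_a[20] <- 1 / 4096
  sparks2 <- structure(list(sp_intensity = sp_i, sp_area = sp_a,
                            n_pixels = 4096, dt = dt, threshold = 10,
                            flagged = FALSE), class = "spark_series")
  expect_equal(transient_metrics(time_series(v, dt), sparks2)$spark_count_before, 2)
})

test_that("dfdt_max scales with transient amplitude (inotropy readout)", {
  dt <- 0.02
  tt <- seq(0, 0.9, by = dt)
  pulse <- function(a) a * (1 - exp(-tt / 0.03)) * exp(-tt / 0.17)
  v <- c(rep(0, 30), pulse(100), rep(0, 5), pulse(150), rep(0, 30))
  tm <- transient_metrics(time_series(v, dt))
  expect_equal(nrow(tm), 2)
  expect_equal(tm$dfdt_max[2] / tm$dfdt_max[1], 1.5, tolerance = 0.05)
})

test_that("a trace with no super-threshold peaks returns empty, not an error", {
  tm <- transient_metrics(time_series(rep(5, 100), 0.02))
  expect_equal(nrow(tm), 0)
  tm2 <- transient_metrics(time_series(seq(0, 1, length.out = 50), 0.02))
  expect_equal(nrow(tm2), 0)
})

test_that("transient summaries drop NA metrics and report rate", {
  tm <- data.frame(t0_s = c(0.1, 1.1), ttp_s = c(0.06, 0.06),
                   t90_s = c(0.4, NA), amplitude = c(50, 52),
                   width10_s = c(0.5, 0.5), dfdt_max = c(900, 910),
                   spark_count_before = c(1, 0), t90_truncated = c(FALSE, TRUE))
  s <- summarize_transients(tm, duration_s = 2)
  expect_equal(s$n_transients, 2)
  expect_equal(s$rate_hz, 1)
  expect_equal(s$metrics$mean[s$metrics$metric == "t90_s"], 0.4)
  expect_true(is.na(s$metrics$sem[s$metrics$metric == "t90_s"]))
})
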