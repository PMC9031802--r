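# Independent oracles used by the unit and acceptance tests.  Each one
# is a deliberately naive, literal implementation kept separate from the
# package code paths it checks.

# Smooth periodic random texture: a sum of integer-frequency sinusoids,
# so a circular integer shift of the matrix equals an exact translation
# of the underlying pattern.  Quantized to 8-bit.
mk_texture <- function(n = 64, K = 10, fmax = 3, seed = 1) {
  set.seed(seed)
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  tx <- matrix(0, n, n)
  for (k in seq_len(K)) {
    fx <- sample(0:fmax, 1); fy <- sample(0:fmax, 1)
    if (fx == 0 && fy == 0) fx <- 1
    tx <- tx + runif(1, 0.3, 1) * sin(2 * pi * (fx * xs + fy * ys) / n +
                                      runif(1, 0, 2 * pi))
  }
  tx <- (tx - min(tx)) / (max(tx) - min(tx))
  round(20 + 215 * tx)
}

# Circular shift: pattern moves right by dx columns, down by dy rows.
circ_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((0:(nr - 1) - dy) %% nr) + 1, ((0:(nc - 1) - dx) %% nc) + 1]
}

# Exhaustive integer-shift cross-correlation (SSD) oracle.
oracle_shift <- function(I1, I2, max_shift = 3) {
  best <- c(NA, NA); best_ssd <- Inf
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      ssd <- sum((circ_shift(I1, dy, dx) - I2)^2)
      if (ssd < best_ssd) {
        best_ssd <- ssd
        best <- c(dx, dy)
      }
    }
  }
  best
}

# Full-sort top-fraction oracle.
oracle_top_fraction <- function(u, v, fraction) {
  mag <- sqrt(as.vector(u)^2 + as.vector(v)^2)
  k <- max(1, floor(fraction * length(mag)))
  mean(mag[order(mag, decreasing = TRUE)][1:k])
}

# Literal brute-force implementation of the velocity-trace peak rules:
# (1) 5% relative amplitude filter, (2) 10th-percentile baseline,
# (3) greedy pairing of close peaks, (4) 20%-above-baseline endpoints,
# (5) delay = gap between first peak end and second peak start.
oracle_peaks <- function(v, baseline, min_rel = 0.05, frac = 0.2) {
  n <- length(v)
  apexes <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        apexes <- c(apexes, i + (j - i) %/% 2L)  # left-centre of plateau
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  apexes <- apexes[v[apexes] > baseline]
  if (length(apexes) == 0L) {
    return(data.frame(start = integer(0), apex = integer(0), end = integer(0)))
  }
  amp <- v[apexes] - baseline
  sel <- amp >= min_rel * max(amp)
  apexes <- apexes[sel]; amp <- amp[sel]
  m <- length(apexes)
  if (m == 0L) {
    return(data.frame(start = integer(0), apex = integer(0), end = integer(0)))
  }
  start <- end <- integer(m)
  for (k in seq_len(m)) {
    lev <- baseline + frac * amp[k]
    lb <- if (k > 1L) apexes[k - 1L] else 1L
    rb <- if (k < m) apexes[k + 1L] else n
    # left
    j <- apexes[k]; found <- FALSE
    while (j - 1L >= lb) {
      if (v[j - 1L] <= lev) {
        start[k] <- round(j - (v[j] - lev) / (v[j] - v[j - 1L]))
        found <- TRUE
        break
      }
      j <- j - 1L
    }
    if (!found) start[k] <- lb
    # right
    j <- apexes[k]; found <- FALSE
    while (j + 1L <= rb) {
      if (v[j + 1L] <= lev) {
        end[k] <- round(j + (v[j] - lev) / (v[j] - v[j + 1L]))
        found <- TRUE
        break
      }
      j <- j + 1L
    }
    if (!found) end[k] <- rb
  }
  data.frame(start = start, apex = apexes, end = end, amplitude = amp)
}

oracle_pair <- function(pk, max_gap_s, dt) {
  pairs <- NULL
  i <- 1L
  while (i < nrow(pk) + 1L) {
    if (i + 1L <= nrow(pk) &&
        (pk$start[i + 1L] - pk$end[i]) * dt <= max_gap_s) {
      pairs <- rbind(pairs, c(i, i + 1L))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  pairs
}

# Random piecewise-linear trace: continuous random knot values linearly
# interpolated onto a regular grid.
random_pl_trace <- function(n = 200, n_knots = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_knots)) n_knots <- sample(5:25, 1)
  kx <- sort(c(1, n, sample(2:(n - 1), n_knots)))
  ky <- runif(length(kx), 0, 100)
  approx(kx, ky, xout = 1:n)$y
}

# Exact permutation p-value for the two-sample mean difference
# (enumerates all reassignments; feasible for n <= 6 + 6).
perm_p_value <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  splits <- combn(length(pooled), nx)
  ps <- apply(splits, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(ps >= obs - 1e-12)
}

# Tiny in-memory video helper.
stack_from_frames <- function(..., fps = 50, channel = "gray") {
  fr <- list(...)
  arr <- array(0, c(nrow(fr[[1]]), ncol(fr[[1]]), length(fr)))
  for (i in seq_along(fr)) arr[, , i] <- fr[[i]]
  video_stack(arr, fps = fps, channel = channel)
}
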