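# Independent naive reimplementations of each index, used as oracles.
# Deliberately direct: explicit loops, stats::cor, no shared machinery with
# the package's windowed engine.

naive_window_corr_mean <- function(x, y, valid, dt, window_s, step_s,
                                   min_valid = 0.75) {
  w <- max(3L, round(window_s / dt))
  s <- max(1L, round(step_s / dt))
  n <- length(x)
  if (n < w) return(NA_real_)
  rs <- numeric(0)
  for (i in seq(1L, n - w + 1L, by = s)) {
    idx <- i:(i + w - 1L)
    v <- valid[idx]
    if (sum(v) < min_valid * w) next
    xv <- x[idx][v]; yv <- y[idx][v]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) next
    rs <- c(rs, stats::cor(xv, yv))
  }
  if (length(rs) == 0L) NA_real_ else mean(rs)
}

naive_prx <- function(seg, window_s = 300, step_s = 60)
  naive_window_corr_mean(seg$map, seg$icp, seg$valid, seg$sample_interval_s,
                         window_s, step_s)

naive_rap <- function(seg, window_s = 240, step_s = 60)
  naive_window_corr_mean(seg$amp, seg$icp, seg$valid, seg$sample_interval_s,
                         window_s, step_s)

naive_dicp <- function(seg, threshold = 20) {
  total <- 0
  for (i in seq_along(seg$icp))
    if (seg$valid[i] && seg$icp[i] > threshold)
      total <- total + (seg$icp[i] - threshold) * seg$sample_interval_s
  total / 3600
}

naive_mean_icp <- function(seg) {
  s <- 0; k <- 0
  for (i in seq_along(seg$icp))
    if (seg$valid[i]) { s <- s + seg$icp[i]; k <- k + 1 }
  s / k
}

naive_cpp <- function(seg) {
  s <- 0; k <- 0
  for (i in seq_along(seg$icp))
    if (seg$valid[i]) { s <- s + seg$map[i] - seg$icp[i]; k <- k + 1 }
  s / k
}

# O(n^2) pair-counting oracles
brute_u1 <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# A random 1200-sample segment with autocorrelated structure and a sprinkle
# of invalid samples, as a trend_series.
random_segment <- function(seed, n = 1200, dropout = 0.1) {
  set.seed(seed)
  drift <- cumsum(rnorm(n, 0, 0.2))
  icp <- 18 + 4 * sin(2 * pi * seq_len(n) * 3 / 75) + drift + rnorm(n, 0, 1)
  map <- 85 + 3 * sin(2 * pi * seq_len(n) * 3 / 60) + 0.5 * drift + rnorm(n, 0, 2)
  amp <- pmax(1.5 + 0.08 * (icp - 18) + rnorm(n, 0, 0.3), 0)
  valid <- rep(TRUE, n)
  valid[sample.int(n, round(dropout * n))] <- FALSE
  trend_series(icp = icp, map = map, amp = amp, valid = valid,
               sample_interval_s = 3)
}

expect_rel_equal <- function(got, want, tol = 1e-9) {
  denom <- max(abs(want), 1e-12)
  expect_lt(abs(got - want) / denom, tol)
}
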