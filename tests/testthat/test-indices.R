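test_that("segmentation arithmetic: window counts, partial flags, valid fractions", {
  ts <- trend_series(icp = numeric(86400), map = numeric(86400),
                     sample_interval_s = 3)
  segs <- segment_trend(ts)
  expect_length(segs, 72)
  expect_true(all(vapply(segs, length, integer(1)) == 1200))
  expect_false(any(vapply(segs, attr, logical(1), "partial")))

  ts2 <- trend_series(icp = numeric(1800), sample_interval_s = 3)
  segs2 <- segment_trend(ts2)
  expect_length(segs2, 2)
  expect_equal(length(segs2[[2]]), 600)
  expect_true(attr(segs2[[2]], "partial"))
  expect_false(attr(segs2[[1]], "partial"))

  v <- rep(TRUE, 1200); v[1:300] <- FALSE
  ts3 <- trend_series(icp = numeric(1200), valid = v, sample_interval_s = 3)
  expect_equal(attr(segment_trend(ts3)[[1]], "valid_fraction"), 0.75)
})

test_that("mean ICP: closed forms, oracle, and the validity threshold", {
  seg <- trend_series(icp = rep(15, 1200), sample_interval_s = 3)
  expect_equal(mean_icp(seg), 15)
  seg2 <- trend_series(icp = rep(c(10, 20), 600), sample_interval_s = 3)
  expect_equal(mean_icp(seg2), 15)
  for (s in 1:5) {
    seg3 <- random_segment(s)
    expect_rel_equal(mean_icp(seg3), naive_mean_icp(seg3))
  }
  v <- rep(c(TRUE, FALSE), c(500, 700))
  seg4 <- trend_series(icp = rnorm(1200, 15), valid = v, sample_interval_s = 3)
  expect_true(is.na(mean_icp(seg4)))        # 42% valid < 50%: missing, not 0
  expect_false(is.na(mean_icp(seg4, min_valid_fraction = 0.4)))
})

test_that("CPP equals mean MAP minus mean ICP on the same valid samples", {
  seg <- trend_series(icp = rep(20, 1200), map = rep(90, 1200),
                      sample_interval_s = 3)
  expect_equal(cpp(seg), 70)
  x <- rnorm(1200, 25, 5)
  seg2 <- trend_series(icp = x, map = x, sample_interval_s = 3)
  expect_equal(cpp(seg2), 0)
  for (s in 6:10) {
    seg3 <- random_segment(s)
    v <- seg3$valid
    expect_equal(cpp(seg3), mean(seg3$map[v]) - mean(seg3$icp[v]))
    expect_rel_equal(cpp(seg3), naive_cpp(seg3), tol = 1e-12)
  }
})

test_that("PRx: perfect coupling, zero variance, and the missing-MAP error", {
  map <- 85 + 5 * sin(seq_len(1200) / 20) + rnorm(1200)
  pos <- trend_series(icp = 0.4 * map + 3, map = map, sample_interval_s = 3)
  expect_equal(prx(pos), 1)
  neg <- trend_series(icp = -map + 120, map = map, sample_interval_s = 3)
  expect_equal(prx(neg), -1)
  flat <- trend_series(icp = rep(12, 1200), map = map, sample_interval_s = 3)
  expect_true(is.na(prx(flat)))             # zero ICP variance: undefined
  nomap <- trend_series(icp = rnorm(1200, 15), sample_interval_s = 3)
  expect_error(prx(nomap), "MAP")
  # one-correlation-per-segment mode
  seg <- random_segment(11)
  whole <- prx(seg, window_s = 3600, step_s = 3600)
  v <- seg$valid
  expect_rel_equal(whole, cor(seg$map[v], seg$icp[v]))
})

test_that("PRx with no coupling and independent noise is near zero on average", {
  vals <- vapply(1:50, function(s) {
    cfg <- sim_config(duration_hours = 1, reactivity_gain = 0,
                      dropout_fraction = 0, seed = 1000 + s)
    prx(segment_trend(simulate_patient(cfg))[[1]])
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("RAP: affine amplitude, undefined on constant amplitude, exhausted regime", {
  icp <- 20 + 5 * sin(seq_len(1200) / 15) + rnorm(1200, 0, 0.5)
  up <- trend_series(icp = icp, amp = 0.1 * icp + 0.5, sample_interval_s = 3)
  expect_equal(rap(up), 1)
  flat <- trend_series(icp = icp, amp = rep(2, 1200), sample_interval_s = 3)
  expect_true(is.na(rap(flat)))
  noamp <- trend_series(icp = icp, sample_interval_s = 3)
  expect_error(rap(noamp), "RAP unavailable")
  # exhausted compensation: amplitude falls as ICP rises above critical
  cfg <- sim_config(duration_hours = 1, icp_baseline = 28, icp_critical = 22,
                    dropout_fraction = 0, seed = 8)
  seg <- segment_trend(simulate_patient(cfg))[[1]]
  expect_lt(rap(seg), 0)
})

test_that("PRx and RAP are invariant under positive affine rescaling of a channel", {
  for (s in 12:14) {
    seg <- random_segment(s)
    seg2 <- seg
    seg2$map <- 2.5 * seg$map - 40
    expect_rel_equal(prx(seg2), prx(seg))
    seg3 <- seg
    seg3$amp <- 0.3 * seg$amp + 1
    expect_rel_equal(rap(seg3), rap(seg))
  }
})

test_that("DICP: closed forms, threshold monotonicity, additivity, gap handling", {
  at_thr <- trend_series(icp = rep(20, 1200), sample_interval_s = 3)
  expect_identical(dicp(at_thr), 0)
  above <- trend_series(icp = rep(25, 1200), sample_interval_s = 3)
  expect_equal(dicp(above), 5)
  for (s in 15:19) {
    seg <- random_segment(s)
    expect_rel_equal(dicp(seg), naive_dicp(seg), tol = 1e-12)
    # monotone non-increasing in the threshold, vanishing at high threshold
    d <- vapply(c(10, 15, 20, 25, 60), function(th) dicp(seg, th), numeric(1))
    expect_true(all(diff(d) <= 0))
    expect_equal(d[5], 0)
    # additive over any partition at sample boundaries
    cut <- sample(2:1199, 1)
    sub <- function(i) trend_series(icp = seg$icp[i], valid = seg$valid[i],
                                    sample_interval_s = 3)
    expect_equal(dicp(sub(1:cut)) + dicp(sub((cut + 1):1200)), dicp(seg))
  }
  # invalid samples contribute nothing
  v <- rep(TRUE, 1200); v[100:400] <- FALSE
  gap <- trend_series(icp = rep(30, 1200), valid = v, sample_interval_s = 3)
  expect_equal(dicp(gap), 10 * sum(v) * 3 / 3600)
})

test_that("patient aggregation: means, the dose total, and exclusion", {
  h1 <- data.frame(segment = 1, mean_icp = 14, mean_cpp = 70, prx = 0.1,
                   rap = 0.2, dicp = 1.5, valid_fraction = 1, partial = FALSE,
                   hours = 1)
  p1 <- patient_indices(h1)
  expect_equal(p1$mean_icp, 14)
  expect_equal(p1$total_dicp, 1.5)
  expect_equal(p1$n_segments, 1)

  h2 <- rbind(h1, h1)
  h2$prx <- c(0.2, 0.4)
  expect_equal(patient_indices(h2)$mean_prx, 0.3)

  # 72 one-hour segments at 4.449 mmHg x h land on the multi-hundred scale
  h3 <- h1[rep(1, 72), ]
  h3$dicp <- 4.449
  expect_equal(patient_indices(h3)$total_dicp, 320.328)

  h4 <- h1
  h4$mean_icp <- NA_real_
  expect_warning(out <- patient_indices(h4), "excluded")
  expect_null(out)
})

test_that("CPPopt recovers a constructed parabolic minimum and refuses degenerate fits", {
  set.seed(21)
  cppv <- runif(72, 55, 85)
  mk_hourly <- function(prxv) data.frame(segment = seq_along(cppv),
                                         mean_icp = 15, mean_cpp = cppv,
                                         prx = prxv, rap = NA, dicp = 0,
                                         valid_fraction = 1, partial = FALSE,
                                         hours = 1)
  h <- mk_hourly(0.01 * (cppv - 70)^2 - 0.2 + rnorm(72, 0, 0.02))
  expect_lt(abs(cppopt(h) - 70), 2.5)
  # monotone relation: upward parabola vertex falls outside the range
  hm <- mk_hourly(0.005 * cppv - 0.3 + rnorm(72, 0, 0.01))
  expect_true(is.na(cppopt(hm)))
  # fewer than 4 populated bins
  h4 <- mk_hourly(0.01 * (cppv - 70)^2 - 0.2)[1:5, ]
  h4$mean_cpp <- c(56, 56, 62, 62, 67)
  res <- cppopt(h4)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "insufficient_bins")
})

test_that("hourly_indices ties the per-segment engines together", {
  ts <- simulate_patient(sim_config(duration_hours = 2.5, seed = 77))
  hi <- hourly_indices(ts)
  expect_equal(nrow(hi), 3)
  expect_true(hi$partial[3])
  expect_true(all(hi$prx >= -1 & hi$prx <= 1, na.rm = TRUE))
  expect_true(all(hi$rap >= -1 & hi$rap <= 1, na.rm = TRUE))
  expect_true(all(hi$dicp >= 0))
  segs <- segment_trend(ts)
  expect_equal(hi$mean_icp[2], mean_icp(segs[[2]]))
  expect_equal(hi$dicp[3], dicp(segs[[3]]))
})
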