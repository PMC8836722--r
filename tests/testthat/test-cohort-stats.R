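test_that("pooled t from raw data matches stats::t.test and its own summaries", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(8 + i, 10, 3)
    y <- rnorm(12, 12, 2)
    mine <- pooled_t(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(unname(mine$statistic), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    from_sum <- pooled_t(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                         mean2 = mean(y), sd2 = sd(y), n2 = length(y))
    expect_equal(unname(from_sum$statistic), unname(mine$statistic),
                 tolerance = 1e-12)
  }
})

test_that("pooled t edge cases: identical groups, degenerate variance, tiny n", {
  id <- pooled_t(mean1 = 5, sd1 = 1, n1 = 10, mean2 = 5, sd2 = 1, n2 = 10)
  expect_equal(unname(id$statistic), 0)
  expect_equal(id$p.value, 1)
  expect_error(pooled_t(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 2, sd2 = 0, n2 = 5),
               "degenerate")
  expect_error(pooled_t(x = 1, y = rnorm(5)), "n >= 2")
})

test_that("Mann-Whitney U: complements, ties, brute-force pairs, and wilcox agreement", {
  set.seed(11)
  for (i in 1:10) {
    x <- round(rnorm(10, 5, 2), 1)   # rounding induces ties
    y <- round(rnorm(10, 6, 2), 1)
    mw <- mann_whitney(x, y)
    expect_equal(sum(mw$estimate), 100)            # U1 + U2 = n1 n2
    expect_equal(unname(mw$estimate["U1"]), brute_u1(x, y))
    expect_equal(unname(mw$statistic), min(mw$estimate))
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mw$p.value, ref$p.value, tolerance = 1e-10)
  }
  tied <- mann_whitney(1:6, 1:6)
  expect_equal(unname(tied$statistic), 18)          # n1 n2 / 2
  expect_equal(tied$p.value, 1)
  sep <- mann_whitney(1:5, 11:16)
  expect_equal(unname(sep$estimate["U1"]), 0)       # sample1 entirely below
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation tracks the exact distribution", {
  set.seed(29)
  x <- rnorm(10); y <- rnorm(10, 0.8)               # continuous: no ties
  approx_p <- mann_whitney(x, y)$p.value
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.02)
})

test_that("2x2 chi-square: Pearson formula, symmetry, and degeneracies", {
  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    ht <- chi_square_2x2(tab)
    # direct-formula oracle over the four cells
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(unname(ht$statistic), sum((tab - e)^2 / e), tolerance = 1e-12)
    expect_equal(unname(ht$parameter), 1)
    # invariant under transposition and row/column swaps
    expect_equal(unname(chi_square_2x2(t(tab))$statistic),
                 unname(ht$statistic), tolerance = 1e-12)
    expect_equal(unname(chi_square_2x2(tab[2:1, ])$statistic),
                 unname(ht$statistic), tolerance = 1e-12)
    expect_equal(unname(chi_square_2x2(tab[, 2:1])$statistic),
                 unname(ht$statistic), tolerance = 1e-12)
  }
  prop <- matrix(c(10, 5, 20, 10), 2)               # perfectly proportional
  expect_equal(unname(chi_square_2x2(prop)$statistic), 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("p values shrink as the statistic grows, at fixed df", {
  ts <- seq(0.5, 6, by = 0.5)
  ps <- vapply(ts, function(t0)
    pooled_t(mean1 = t0, sd1 = sqrt(13), n1 = 26,
             mean2 = 0, sd2 = sqrt(13.5), n2 = 27)$p.value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("descriptive summaries match brute-force order statistics", {
  d <- describe_group(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(describe_group(c(1, 2, 3, 4))$median, 2.5)
  set.seed(7)
  x <- rnorm(37)
  d2 <- describe_group(x, "nonparametric")
  # type-7 linear interpolation by hand on the sorted sample
  q7 <- function(p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  expect_equal(d2$median, q7(0.5))
  expect_equal(d2$iqr, q7(0.75) - q7(0.25))
  expect_error(describe_group(1), "at least 2")
})

test_that("the baseline comparison table carries the configured tests and group sizes", {
  set.seed(13)
  mk_group <- function(n, group, icp, prx)
    data.frame(group = group, age = rnorm(n, 64, 12),
               sex = sample(c("male", "female"), n, TRUE),
               gcs = sample(4:9, n, TRUE),
               hematoma_ml = rnorm(n, 36, 6),
               mean_icp = rnorm(n, icp, 4), mean_prx = rnorm(n, prx, 0.1),
               mean_rap = rnorm(n, 0.2, 0.1), mean_cpp = rnorm(n, 65, 10),
               total_dicp = rexp(n, 1 / 100))
  patients <- rbind(mk_group(27, "good", 10, 0.05), mk_group(26, "poor", 27, 0.34))
  t1 <- build_table1(patients)
  expect_s3_class(t1, "icp_table1")
  expect_equal(nrow(t1), 9)
  expect_true(all(t1$good_n == 27))
  expect_true(all(t1$poor_n == 26))
  expect_equal(t1$test[t1$variable == "sex"], "chi_square")
  expect_equal(t1$test[t1$variable == "total_dicp"], "mann_whitney")
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
  # strongly separated variables are detected
  expect_lt(t1$p_value[t1$variable == "mean_icp"], 0.001)
  expect_error(build_table1(patients, c(nonexistent = "pooled_t")),
               "nonexistent")
  expect_error(build_table1(patients, c(age = "anova")), "unknown test")
})
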