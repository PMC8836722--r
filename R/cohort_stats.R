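#' Two-sample pooled-variance (Student) t test
#'
#' Equal-variance two-sample t test, callable either on raw samples (`x`,
#' `y`) or directly on printed summary statistics (mean, SD, n per group) —
#' the latter is what lets published baseline tables be re-checked without
#' patient-level data. Both routes use the same formula, so raw data and
#' their own summaries give identical results.
#'
#' @param x,y raw samples (optional; summaries are computed from them).
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics (used when `x`
#'   and `y` are not given). SDs are sample SDs (n − 1 denominator).
#' @return an object of class `htest` with the t statistic, `df = n1 + n2 −
#'   2` and the two-sided p value.
#' @export
#' @examples
#' pooled_t(mean1 = 27.68, sd1 = 13.17, n1 = 26,
#'          mean2 = 10.12, sd2 = 4.37, n2 = 27)
pooled_t <- function(x = NULL, y = NULL,
                     mean1 = NULL, sd1 = NULL, n1 = NULL,
                     mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2L || length(y) < 2L)
      stop("both samples need n >= 2", call. = FALSE)
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
    dname <- "x and y"
  } else {
    dname <- "summary statistics"
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2))
    stop("supply either raw samples or full summaries for both groups",
         call. = FALSE)
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("degenerate variance: both groups are constant", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p,
                 estimate = c(`mean of group 1` = mean1,
                              `mean of group 2` = mean2),
                 method = "Two-sample pooled-variance t test",
                 data.name = dname),
            class = "htest")
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Rank-sum comparison of two samples. U1 counts pairs where `x > y` plus
#' half of the tied pairs; `U2 = n1 * n2 - U1`; the reported U statistic is
#' `min(U1, U2)`, the SPSS convention in which published tables print it.
#' The p value uses the normal approximation with tie-corrected variance and
#' a 0.5 continuity correction, two-sided — appropriate at the cohort sizes
#' this test is meant for (an exact-enumeration oracle for small samples
#' lives in the test suite).
#'
#' @param x,y non-empty numeric samples.
#' @return an object of class `htest`; the `statistic` is `min(U1, U2)` and
#'   `estimate` carries `U1` and `U2`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2         # pairs x > y, ties half
  u2 <- n1 * n2 - u1
  u_gt <- u1
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    z <- 0; p <- 1                      # all observations tied
  } else {
    z <- (u_gt - mu - sign(u_gt - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(U = min(u1, u2)),
                 parameter = c(z = z),
                 p.value = min(p, 1),
                 estimate = c(U1 = u1, U2 = u2),
                 method = "Mann-Whitney U test (normal approximation, tie-corrected)",
                 data.name = "x and y"),
            class = "htest")
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' Uncorrected Pearson chi-square with 1 degree of freedom — the form under
#' which published 2x2 comparisons (e.g. sex ratios between outcome groups)
#' are reproducible.
#'
#' @param table a 2x2 matrix of counts with all marginals positive.
#' @return an object of class `htest` (from [stats::chisq.test()]).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  if (any(rowSums(table) <= 0) || any(colSums(table) <= 0))
    stop("all row and column marginals must be positive", call. = FALSE)
  suppressWarnings(stats::chisq.test(table, correct = FALSE))
}

#' Descriptive group summary
#'
#' Mean/SD (sample SD) for normally distributed variables, median/IQR for
#' the rest; both are always computed, the `style` records which pair is the
#' primary description. Quartiles use R's default linear-interpolation
#' convention (type 7).
#'
#' @param x numeric sample with `n >= 2`.
#' @param style `"normal"` (mean ± SD) or `"nonparametric"` (median, IQR).
#' @return list with `n`, `mean`, `sd`, `median`, `iqr`, `style`.
#' @export
describe_group <- function(x, style = c("normal", "nonparametric")) {
  style <- match.arg(style)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite observations", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       median = q[2], iqr = q[3] - q[1], style = style)
}

#' Default test assignment for the baseline comparison table
#'
#' Which test each baseline variable gets: pooled t for age, hematoma
#' volume and the four mean indices; Mann-Whitney for GCS and the DICP
#' dose; chi-square for sex. Mirrors the fixed choices of the study design
#' this layout reproduces (normality is a stated assumption, not re-tested
#' per run).
#'
#' @return named character vector mapping variable to
#'   `"pooled_t" | "mann_whitney" | "chi_square"`.
#' @export
default_table1_tests <- function() {
  c(age = "pooled_t", sex = "chi_square", gcs = "mann_whitney",
    hematoma_ml = "pooled_t", mean_icp = "pooled_t", mean_prx = "pooled_t",
    mean_rap = "pooled_t", mean_cpp = "pooled_t", total_dicp = "mann_whitney")
}

#' Two-group baseline comparison table
#'
#' Builds the standard baseline table: one row per variable with per-group
#' descriptive summaries and the assigned hypothesis test (pooled t,
#' Mann-Whitney U, or chi-square for sex). Input is the patient-level table
#' from [cohort_indices()] (or any data.frame with a `group` column holding
#' `"good"`/`"poor"`).
#'
#' @param patients data.frame with `group` plus the variables in `tests`.
#' @param tests named character vector mapping variable to test; see
#'   [default_table1_tests()]. Unknown test names are an error.
#' @return data.frame of class `icp_table1`: `variable`, `test`,
#'   `good_n`, `good_mean`, `good_sd`, `good_median`, `good_iqr`, the same
#'   for `poor`, `statistic`, `df`, `p_value`.
#' @export
build_table1 <- function(patients, tests = default_table1_tests()) {
  stopifnot(is.data.frame(patients), "group" %in% names(patients))
  good <- patients[patients$group == "good", , drop = FALSE]
  poor <- patients[patients$group == "poor", , drop = FALSE]
  if (nrow(good) < 2L || nrow(poor) < 2L)
    stop("both groups must have at least 2 patients", call. = FALSE)
  rows <- lapply(names(tests), function(v) {
    test <- tests[[v]]
    if (!test %in% c("pooled_t", "mann_whitney", "chi_square"))
      stop(sprintf("unknown test '%s' for variable '%s'", test, v),
           call. = FALSE)
    if (!v %in% names(patients))
      stop(sprintf("variable '%s' not found in the patient table", v),
           call. = FALSE)
    if (test == "chi_square") {
      tab <- table(factor(patients$group, c("good", "poor")), patients[[v]])
      ht <- chi_square_2x2(tab)
      data.frame(variable = v, test = test,
                 good_n = nrow(good), good_mean = NA_real_, good_sd = NA_real_,
                 good_median = NA_real_, good_iqr = NA_real_,
                 poor_n = nrow(poor), poor_mean = NA_real_, poor_sd = NA_real_,
                 poor_median = NA_real_, poor_iqr = NA_real_,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter["df"]),
                 p_value = ht$p.value)
    } else {
      xg <- good[[v]]; xp <- poor[[v]]
      if (sum(is.finite(xg)) < 2L || sum(is.finite(xp)) < 2L)
        stop(sprintf(
          "variable '%s': fewer than 2 defined values in a group", v),
          call. = FALSE)
      style <- if (test == "pooled_t") "normal" else "nonparametric"
      dg <- describe_group(xg, style); dp <- describe_group(xp, style)
      ht <- if (test == "pooled_t") pooled_t(x = xg, y = xp)
            else mann_whitney(xg, xp)
      data.frame(variable = v, test = test,
                 good_n = dg$n, good_mean = dg$mean, good_sd = dg$sd,
                 good_median = dg$median, good_iqr = dg$iqr,
                 poor_n = dp$n, poor_mean = dp$mean, poor_sd = dp$sd,
                 poor_median = dp$median, poor_iqr = dp$iqr,
                 statistic = unname(ht$statistic),
                 df = if (test == "pooled_t") unname(ht$parameter["df"])
                      else NA_real_,
                 p_value = ht$p.value)
    }
  })
  structure(do.call(rbind, rows), class = c("icp_table1", "data.frame"))
}

#' @export
print.icp_table1 <- function(x, digits = 3, ...) {
  cat("Two-group baseline comparison (good vs poor prognosis)\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    desc <- switch(r$test,
      pooled_t = sprintf("good %.2f +/- %.2f | poor %.2f +/- %.2f, t = %.3f (df %d)",
                         r$good_mean, r$good_sd, r$poor_mean, r$poor_sd,
                         r$statistic, as.integer(r$df)),
      mann_whitney = sprintf("good %.2f (IQR %.2f) | poor %.2f (IQR %.2f), U = %.1f",
                             r$good_median, r$good_iqr, r$poor_median,
                             r$poor_iqr, r$statistic),
      chi_square = sprintf("chi-square = %.3f (df %d)", r$statistic,
                           as.integer(r$df)))
    cat(sprintf("  %-12s %s, p = %s\n", r$variable, desc,
                format.pval(r$p_value, digits = digits)))
  }
  invisible(x)
}
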