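as_is_poor <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("good", "poor")))
      stop("character labels must be 'good'/'poor'", call. = FALSE)
    return(labels == "poor")
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be logical, 0/1, or 'good'/'poor'", call. = FALSE)
}

#' Empirical ROC curve for predicting poor prognosis
#'
#' Builds the empirical ROC curve of a patient-level score against the
#' outcome. The predictive direction is explicit and never auto-flipped: for
#' `"higher_is_poor"` a patient is called poor when the score is at or above
#' the threshold; for `"lower_is_poor"` scores are negated first (an index
#' like CPP, where the good-outcome group runs higher, uses this). An
#' anti-predictive index therefore shows up honestly as AUC < 0.5 (a message
#' flags AUC well below chance as a likely mis-specified direction).
#'
#' The curve is evaluated at every distinct score value and includes the
#' endpoints (0, 0) and (1, 1); the AUC is the trapezoidal area, which
#' equals the normalised Mann-Whitney statistic, ties counted half.
#'
#' @param scores numeric predictor, one value per patient.
#' @param labels outcome labels: logical (TRUE = poor), 0/1 or
#'   `"good"`/`"poor"`.
#' @param direction `"higher_is_poor"` or `"lower_is_poor"`.
#' @param variable display name for reports.
#' @return object of class `icp_roc`: list with `curve` (data.frame
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `direction`,
#'   `variable`, `n_poor`, `n_good`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("higher_is_poor", "lower_is_poor"),
                      variable = "score") {
  direction <- match.arg(direction)
  is_poor <- as_is_poor(labels)
  ok <- is.finite(scores) & !is.na(is_poor)
  scores <- scores[ok]; is_poor <- is_poor[ok]
  if (!any(is_poor) || all(is_poor))
    stop("both outcome classes must be present", call. = FALSE)
  s <- if (direction == "lower_is_poor") -scores else scores
  pos <- s[is_poor]; neg <- s[!is_poor]
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  thr_out <- c(Inf, thr, -Inf)
  if (direction == "lower_is_poor") thr_out <- -thr_out
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  if (auc < 0.4)
    message(sprintf(
      "AUC for '%s' is %.3f (< 0.5): the direction flag may be mis-specified",
      variable, auc))
  structure(list(
    curve = data.frame(threshold = thr_out, sensitivity = tpr,
                       specificity = 1 - fpr),
    auc = auc, direction = direction, variable = variable,
    n_poor = length(pos), n_good = length(neg),
    .pos = pos, .neg = neg),
    class = "icp_roc")
}

#' Area under an ROC curve
#' @param roc an [roc_curve()] result.
#' @return the trapezoidal AUC, in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "icp_roc"))
  roc$auc
}

#' Confidence interval for an AUC
#'
#' DeLong's covariance-based interval (default) from the placement values of
#' cases and controls, or the Hanley-McNeil variance formula. The DeLong
#' interval is constructed on the logit scale and back-transformed — the
#' standard small-sample construction, which respects the `[0, 1]` range and
#' stays calibrated when the AUC is close to 1, where the untransformed Wald
#' interval undercovers. For a degenerate AUC (0 or 1, zero variance) it
#' falls back to the truncated Wald form. Hanley-McNeil is a plain
#' normal-theory interval truncated to `[0, 1]`.
#'
#' @param roc an [roc_curve()] result with `>= 2` patients per class.
#' @param method `"delong"` or `"hanley_mcneil"`.
#' @param level confidence level (default 0.95).
#' @return named numeric: `ci_low`, `ci_high` (attribute `se`, the standard
#'   error of the AUC itself).
#' @export
auc_ci <- function(roc, method = c("delong", "hanley_mcneil"), level = 0.95) {
  stopifnot(inherits(roc, "icp_roc"))
  method <- match.arg(method)
  pos <- roc$.pos; neg <- roc$.neg
  m <- length(pos); n <- length(neg)
  if (m < 2L || n < 2L)
    stop("confidence intervals need at least 2 patients per class",
         call. = FALSE)
  a <- roc$auc
  z <- stats::qnorm((1 + level) / 2)
  if (method == "delong") {
    psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    v10 <- rowMeans(psi)   # placement of each case among controls
    v01 <- colMeans(psi)
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    if (a > 0 && a < 1 && se > 0) {
      se_logit <- se / (a * (1 - a))
      lo <- stats::plogis(stats::qlogis(a) - z * se_logit)
      hi <- stats::plogis(stats::qlogis(a) + z * se_logit)
      ci <- c(ci_low = lo, ci_high = hi)
      attr(ci, "se") <- se
      return(ci)
    }
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
                 (m * n))
  }
  ci <- c(ci_low = max(0, a - z * se), ci_high = min(1, a + z * se))
  attr(ci, "se") <- se
  ci
}

#' @export
print.icp_roc <- function(x, ...) {
  cat(sprintf("<icp_roc> %s (%s): AUC = %.3f  [%d poor vs %d good]\n",
              x$variable, x$direction, x$auc, x$n_poor, x$n_good))
  invisible(x)
}

#' Default prognostic directions for the patient-level indices
#'
#' Mean ICP, PRx, RAP and the DICP dose predict poor outcome when high; CPP
#' predicts poor outcome when low (the good-prognosis group runs higher
#' perfusion pressure).
#'
#' @return named character vector variable -> direction.
#' @export
default_roc_directions <- function() {
  c(mean_icp = "higher_is_poor", mean_prx = "higher_is_poor",
    mean_rap = "higher_is_poor", total_dicp = "higher_is_poor",
    mean_cpp = "lower_is_poor")
}

#' Rank patient-level indices by prognostic discrimination
#'
#' Computes an ROC curve with confidence interval for each index and sorts
#' by AUC, descending.
#'
#' @param patients patient-level data.frame with a `group` column
#'   (`"good"`/`"poor"`) and the index columns named in `directions`.
#' @param directions named character vector of per-variable directions; see
#'   [default_roc_directions()]. A missing column is an error naming it.
#' @param ci_method,level passed to [auc_ci()].
#' @return data.frame `variable`, `direction`, `auc`, `ci_low`, `ci_high`,
#'   `ci_method`, sorted by `auc` descending; attribute `curves` holds the
#'   `icp_roc` objects.
#' @export
rank_predictors <- function(patients, directions = default_roc_directions(),
                            ci_method = "delong", level = 0.95) {
  stopifnot(is.data.frame(patients), "group" %in% names(patients))
  if (length(directions) < 2L)
    stop("need at least 2 index variables to rank", call. = FALSE)
  missing_cols <- setdiff(names(directions), names(patients))
  if (length(missing_cols))
    stop(sprintf("missing index column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  curves <- lapply(names(directions), function(v)
    roc_curve(patients[[v]], patients$group, directions[[v]], variable = v))
  cis <- lapply(curves, auc_ci, method = ci_method, level = level)
  out <- data.frame(
    variable = names(directions),
    direction = unname(directions),
    auc = vapply(curves, roc_auc, numeric(1)),
    ci_low = vapply(cis, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(cis, `[[`, numeric(1), "ci_high"),
    ci_method = ci_method)
  ord <- order(out$auc, decreasing = TRUE)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "curves") <- curves[ord]
  out
}
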