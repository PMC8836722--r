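#' Uniformly sampled neuromonitoring trend series
#'
#' Container for one patient's trend recording: mean intracranial pressure
#' (ICP), mean arterial pressure (MAP) and, optionally, the ICP pulse
#' amplitude (AMP), all sampled on a common uniform grid (3-second intervals
#' on typical bedside exports). Samples affected by artifacts or probe
#' disconnection are kept in place and flagged invalid, so that segmentation
#' arithmetic stays index-based.
#'
#' @param icp numeric vector, mean ICP in mmHg.
#' @param map numeric vector, mean arterial pressure in mmHg, or `NULL` if
#'   the channel is absent (PRx and CPP are then unavailable).
#' @param amp numeric vector, ICP pulse amplitude in mmHg, or `NULL` if the
#'   channel is absent (RAP is then unavailable).
#' @param valid logical vector flagging usable samples; defaults to all
#'   `TRUE`.
#' @param sample_interval_s sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds.
#'
#' @return An object of class `trend_series`: a list with elements
#'   `sample_interval_s`, `t0`, `icp`, `map`, `amp`, `valid`.
#' @export
#' @examples
#' ts <- trend_series(icp = rep(12, 100), map = rep(85, 100),
#'                    sample_interval_s = 3)
#' length(ts)
trend_series <- function(icp, map = NULL, amp = NULL, valid = NULL,
                         sample_interval_s = 3, t0 = 0) {
  if (!is.numeric(icp) || length(icp) < 1L)
    stop("'icp' must be a non-empty numeric vector", call. = FALSE)
  n <- length(icp)
  if (!is.null(map) && length(map) != n)
    stop("'map' must match the length of 'icp'", call. = FALSE)
  if (!is.null(amp) && length(amp) != n)
    stop("'amp' must match the length of 'icp'", call. = FALSE)
  valid <- valid %||% rep(TRUE, n)
  if (!is.logical(valid) || length(valid) != n)
    stop("'valid' must be a logical vector matching 'icp'", call. = FALSE)
  check_scalar(sample_interval_s, "sample_interval_s", lower = 0, strict_lower = TRUE)
  structure(
    list(sample_interval_s = sample_interval_s, t0 = t0,
         icp = as.numeric(icp),
         map = if (is.null(map)) NULL else as.numeric(map),
         amp = if (is.null(amp)) NULL else as.numeric(amp),
         valid = valid),
    class = "trend_series")
}

#' @export
length.trend_series <- function(x) length(x$icp)

#' @export
print.trend_series <- function(x, ...) {
  n <- length(x)
  dur_h <- n * x$sample_interval_s / 3600
  cat(sprintf("<trend_series> %d samples @ %gs (%.2f h)%s%s, %.1f%% valid\n",
              n, x$sample_interval_s, dur_h,
              if (is.null(x$map)) ", MAP absent" else "",
              if (is.null(x$amp)) ", AMP absent" else "",
              100 * mean(x$valid)))
  invisible(x)
}

#' Fraction of valid samples
#' @param series a [trend_series()] (or segment thereof).
#' @return proportion of samples flagged valid, in `[0, 1]`.
#' @export
valid_fraction <- function(series) mean(series$valid)

#' Split a trend series into consecutive fixed-duration segments
#'
#' Splits into non-overlapping windows of `segment_hours` (1 h in the standard
#' analysis). A trailing window shorter than the nominal length is kept and
#' flagged partial; downstream index means skip it or weight it by duration as
#' appropriate for each index.
#'
#' @param series a [trend_series()].
#' @param segment_hours segment duration in hours (default 1).
#' @return list of `trend_series` segments, each carrying attributes
#'   `segment_index` (1-based), `partial` (logical) and `valid_fraction`.
#' @export
segment_trend <- function(series, segment_hours = 1) {
  stopifnot(inherits(series, "trend_series"))
  n <- length(series)
  if (n < 1L) stop("cannot segment an empty series", call. = FALSE)
  check_scalar(segment_hours, "segment_hours", lower = 0, strict_lower = TRUE)
  w <- floor(3600 * segment_hours / series$sample_interval_s)
  if (w < 1L) stop("segment shorter than one sample", call. = FALSE)
  n_seg <- ceiling(n / w)
  lapply(seq_len(n_seg), function(k) {
    i0 <- (k - 1L) * w + 1L
    i1 <- min(k * w, n)
    idx <- i0:i1
    seg <- trend_series(
      icp = series$icp[idx],
      map = if (is.null(series$map)) NULL else series$map[idx],
      amp = if (is.null(series$amp)) NULL else series$amp[idx],
      valid = series$valid[idx],
      sample_interval_s = series$sample_interval_s,
      t0 = series$t0 + (i0 - 1L) * series$sample_interval_s)
    attr(seg, "segment_index") <- k
    attr(seg, "partial") <- (i1 - i0 + 1L) < w
    attr(seg, "valid_fraction") <- mean(series$valid[idx])
    seg
  })
}
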