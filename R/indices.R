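# Sliding-window Pearson correlations over a pair of channels with an
# invalid-sample mask. Channels are centred on their valid-sample means first
# so the running sums stay well conditioned; Pearson correlation is invariant
# under the shift. Windows with too few valid samples or with (numerically)
# zero variance in either channel yield NA rather than 0: a zero-variance
# window carries no information about coupling.
rolling_corr <- function(x, y, valid, w, step, min_window_valid = 0.75) {
  n <- length(x)
  if (w < 3L || n < w) return(numeric(0))
  v <- as.numeric(valid)
  nv <- sum(v)
  mx <- if (nv > 0) sum(x[valid]) / nv else 0
  my <- if (nv > 0) sum(y[valid]) / nv else 0
  x0 <- ifelse(valid, x - mx, 0)
  y0 <- ifelse(valid, y - my, 0)
  wsum <- function(z) {
    cz <- cumsum(z)
    cz[w:n] - c(0, cz[seq_len(n - w)])
  }
  starts <- seq.int(1L, n - w + 1L, by = step)
  Sv  <- wsum(v)[starts]
  Sx  <- wsum(x0)[starts];      Sy  <- wsum(y0)[starts]
  Sxx <- wsum(x0 * x0)[starts]; Syy <- wsum(y0 * y0)[starts]
  Sxy <- wsum(x0 * y0)[starts]
  dx <- Sv * Sxx - Sx * Sx
  dy <- Sv * Syy - Sy * Sy
  num <- Sv * Sxy - Sx * Sy
  # relative zero-variance guard: exact-constant windows give dx ~ 1e-16*scale
  ok <- Sv >= min_window_valid * w &
    dx > 1e-10 * (Sv * Sxx) & dy > 1e-10 * (Sv * Syy) &
    dx > 0 & dy > 0
  r <- rep(NA_real_, length(starts))
  r[ok] <- num[ok] / sqrt(dx[ok] * dy[ok])
  pmin(1, pmax(-1, r))
}

segment_window_params <- function(segment, window_s, step_s) {
  dt <- segment$sample_interval_s
  list(w = max(3L, as.integer(round(window_s / dt))),
       step = max(1L, as.integer(round(step_s / dt))))
}

#' Mean ICP of a segment
#'
#' Arithmetic mean of ICP over valid samples. Segments with fewer than
#' `min_valid_fraction` valid samples return `NA` (missing, never zero).
#'
#' @param segment a [trend_series()] segment.
#' @param min_valid_fraction minimum proportion of valid samples (default 0.5).
#' @return mean ICP in mmHg, or `NA_real_`.
#' @export
mean_icp <- function(segment, min_valid_fraction = 0.5) {
  if (mean(segment$valid) < min_valid_fraction) return(NA_real_)
  mean(segment$icp[segment$valid])
}

#' Cerebral perfusion pressure of a segment
#'
#' CPP = MAP − ICP, averaged over the same valid samples, so the identity
#' `cpp == mean(MAP) − mean(ICP)` holds exactly.
#'
#' @inheritParams mean_icp
#' @return mean CPP in mmHg, or `NA_real_`.
#' @export
cpp <- function(segment, min_valid_fraction = 0.5) {
  if (is.null(segment$map))
    stop("CPP requires the MAP channel; it is absent from this series",
         call. = FALSE)
  if (mean(segment$valid) < min_valid_fraction) return(NA_real_)
  v <- segment$valid
  mean(segment$map[v]) - mean(segment$icp[v])
}

#' Pressure reactivity index (PRx) of a segment
#'
#' Moving Pearson correlation between the MAP and ICP trends: within each
#' sliding window the correlation of valid (MAP, ICP) sample pairs is taken;
#' the segment PRx is the mean of the window correlations. Negative or
#' near-zero PRx indicates intact cerebrovascular pressure reactivity,
#' positive PRx impaired reactivity. Windows with under `min_window_valid`
#' valid samples, or zero variance in either channel, are skipped; if no
#' window qualifies the segment PRx is `NA`.
#'
#' The default 5-minute window / 1-minute step is the established
#' neuromonitoring convention, applied directly to the 3-second trend samples
#' (the input is already a multi-second trend, so no re-averaging is done).
#' Setting `window_s` to the segment length recovers one correlation per
#' segment.
#'
#' @param segment a [trend_series()] segment with MAP present.
#' @param window_s correlation window in seconds (default 300).
#' @param step_s window step in seconds (default 60).
#' @param min_window_valid minimum valid fraction per window (default 0.75).
#' @return PRx in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
prx <- function(segment, window_s = 300, step_s = 60, min_window_valid = 0.75) {
  if (is.null(segment$map))
    stop("PRx requires the MAP channel; it is absent from this series",
         call. = FALSE)
  p <- segment_window_params(segment, window_s, step_s)
  r <- rolling_corr(segment$map, segment$icp, segment$valid,
                    p$w, p$step, min_window_valid)
  if (length(r) == 0L || all(is.na(r))) return(NA_real_)
  mean(r, na.rm = TRUE)
}

#' Compensatory reserve index (RAP) of a segment
#'
#' Moving Pearson correlation between the ICP pulse amplitude (AMP) and mean
#' ICP, computed with the same sliding-window machinery as [prx()]. RAP near
#' 0 indicates good compensatory reserve (volume changes barely move ICP),
#' RAP near 1 the steep zone of the pressure-volume curve, and negative RAP
#' exhausted compensation, where amplitude falls as ICP keeps rising. The
#' 4-minute default window corresponds to the conventional ~40-sample
#' correlation on multi-second averages.
#'
#' @param segment a [trend_series()] segment with AMP present.
#' @param window_s correlation window in seconds (default 240).
#' @param step_s window step in seconds (default 60).
#' @param min_window_valid minimum valid fraction per window (default 0.75).
#' @return RAP in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
rap <- function(segment, window_s = 240, step_s = 60, min_window_valid = 0.75) {
  if (is.null(segment$amp))
    stop("RAP unavailable: the AMP channel is absent from this series",
         call. = FALSE)
  p <- segment_window_params(segment, window_s, step_s)
  r <- rolling_corr(segment$amp, segment$icp, segment$valid,
                    p$w, p$step, min_window_valid)
  if (length(r) == 0L || all(is.na(r))) return(NA_real_)
  mean(r, na.rm = TRUE)
}

#' Pressure-time dose of ICP above a threshold (DICP)
#'
#' Area between the ICP curve and a treatment threshold (20 mmHg by default,
#' the recommended ICP threshold in hypertensive intracerebral hemorrhage),
#' counting only the excess above the threshold, in mmHg x h. Each valid
#' sample contributes its clipped excess over its own sampling interval;
#' this equals the trapezoidal rule on the clipped curve within runs of
#' consecutive valid samples, extended by half an interval at each run end.
#' Runs broken by invalid samples are integrated separately — no pressure is
#' invented across gaps. The dose is therefore exactly additive over any
#' partition of the segment at sample boundaries, is monotone non-increasing
#' in the threshold, and is zero iff no valid sample exceeds the threshold.
#'
#' @param segment a [trend_series()] segment.
#' @param threshold ICP threshold in mmHg (default 20).
#' @return dose in mmHg x h, `>= 0`.
#' @export
dicp <- function(segment, threshold = 20) {
  if (length(segment$icp) == 0L) stop("empty segment", call. = FALSE)
  ex <- pmax(segment$icp - threshold, 0)
  sum(ex[segment$valid]) * segment$sample_interval_s / 3600
}

#' Hourly monitoring indices of a trend series
#'
#' Splits a recording into fixed segments (1 h by default) and computes mean
#' ICP, mean CPP, PRx, RAP and DICP per segment. Undefined indices are
#' reported as `NA`, never imputed.
#'
#' @param series a [trend_series()].
#' @param segment_hours segment duration in hours.
#' @param threshold DICP threshold, mmHg.
#' @param prx_window_s,rap_window_s correlation windows, seconds.
#' @param corr_step_s correlation window step, seconds.
#' @param min_valid_fraction minimum valid fraction per segment for the mean
#'   pressures.
#' @param min_window_valid minimum valid fraction per correlation window.
#' @param compute_rap compute RAP? Defaults to whether AMP is present.
#' @return data.frame with one row per segment: `segment`, `mean_icp`,
#'   `mean_cpp`, `prx`, `rap`, `dicp`, `valid_fraction`, `partial`, `hours`.
#' @export
hourly_indices <- function(series, segment_hours = 1, threshold = 20,
                           prx_window_s = 300, rap_window_s = 240,
                           corr_step_s = 60,
                           min_valid_fraction = 0.5, min_window_valid = 0.75,
                           compute_rap = !is.null(series$amp)) {
  segs <- segment_trend(series, segment_hours)
  if (compute_rap && is.null(series$amp))
    stop("RAP unavailable: the AMP channel is absent from this series",
         call. = FALSE)
  has_map <- !is.null(series$map)
  rows <- lapply(segs, function(seg) {
    data.frame(
      segment = attr(seg, "segment_index"),
      mean_icp = mean_icp(seg, min_valid_fraction),
      mean_cpp = if (has_map) cpp(seg, min_valid_fraction) else NA_real_,
      prx = if (has_map) prx(seg, prx_window_s, corr_step_s, min_window_valid)
            else NA_real_,
      rap = if (compute_rap) rap(seg, rap_window_s, corr_step_s, min_window_valid)
            else NA_real_,
      dicp = dicp(seg, threshold),
      valid_fraction = attr(seg, "valid_fraction"),
      partial = attr(seg, "partial"),
      hours = length(seg) * seg$sample_interval_s / 3600)
  })
  do.call(rbind, rows)
}

#' Aggregate hourly indices to patient level
#'
#' Patient-level summaries over the monitoring period: means over defined
#' segments for mean ICP, CPP, PRx and RAP; the monitoring-period total for
#' DICP (a dose accumulates — hundreds of mmHg x h over multi-day
#' recordings). Partial trailing segments are weighted by duration in the
#' DICP total only, which is automatic because DICP is a time integral.
#'
#' @param hourly data.frame from [hourly_indices()].
#' @return one-row data.frame with `mean_icp`, `mean_cpp`, `mean_prx`,
#'   `mean_rap`, `total_dicp`, `n_segments`, or `NULL` (with a warning giving
#'   the reason) if no segment has a defined mean ICP.
#' @export
patient_indices <- function(hourly) {
  def <- is.finite(hourly$mean_icp)
  if (!any(def)) {
    warning("patient excluded: no segment reached the minimum valid fraction",
            call. = FALSE)
    return(NULL)
  }
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(
    mean_icp = mean(hourly$mean_icp[def]),
    mean_cpp = mean_def(hourly$mean_cpp),
    mean_prx = mean_def(hourly$prx),
    mean_rap = mean_def(hourly$rap),
    total_dicp = sum(hourly$dicp, na.rm = TRUE),
    n_segments = sum(def))
}

#' Optimal cerebral perfusion pressure (CPPopt) from hourly indices
#'
#' Bins hourly segments by mean CPP (5 mmHg bins by default), averages PRx
#' per bin, and fits a quadratic to (bin centre, mean PRx). If the parabola
#' opens upward and its vertex lies inside the observed CPP range, the vertex
#' abscissa — the CPP at which pressure reactivity is best (PRx minimal) —
#' is returned; otherwise `NA` with a `reason` attribute
#' (`"insufficient_bins"`, `"no_convex_minimum"` or
#' `"vertex_outside_range"`).
#'
#' @param hourly data.frame from [hourly_indices()].
#' @param bin_width CPP bin width, mmHg.
#' @param min_bins minimum number of populated bins (default 4).
#' @param min_per_bin minimum segments per bin (default 2).
#' @return CPPopt in mmHg, or `NA_real_` with attribute `reason`.
#' @export
cppopt <- function(hourly, bin_width = 5, min_bins = 4, min_per_bin = 2) {
  ok <- is.finite(hourly$mean_cpp) & is.finite(hourly$prx)
  cppv <- hourly$mean_cpp[ok]
  prv <- hourly$prx[ok]
  undef <- function(reason) structure(NA_real_, reason = reason)
  if (length(cppv) == 0L) return(undef("insufficient_bins"))
  bin <- floor(cppv / bin_width)
  tab <- table(bin)
  keep <- as.numeric(names(tab)[tab >= min_per_bin])
  if (length(keep) < min_bins) return(undef("insufficient_bins"))
  centers <- (keep + 0.5) * bin_width
  pbar <- vapply(keep, function(b) mean(prv[bin == b]), numeric(1))
  fit <- stats::lm(pbar ~ centers + I(centers^2))
  a <- unname(stats::coef(fit)[3])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(a) || a <= 0) return(undef("no_convex_minimum"))
  v <- -b / (2 * a)
  if (v < min(cppv) || v > max(cppv)) return(undef("vertex_outside_range"))
  v
}
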