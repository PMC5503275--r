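#' Flag artifactual beats by running-median deviation
#'
#' Marks beats whose R-R interval deviates from the running median of the
#' surrounding valid beats by more than a relative threshold. This is the
#' standard robust rule for R-R cleaning: missed R-wave detections merge two
#' intervals into one long interval, spurious detections split an interval
#' into short ones, and both stand out against the local median.
#'
#' For each beat the reference is the median R-R of the valid beats within
#' `half_window` positions on either side (the beat itself excluded). Beats
#' deviating by more than `rel_threshold * median` are flagged `"missed"`
#' (too long) or `"false_positive"` (too short). Beats outside the
#' physiologic range (100, 3000) ms are always flagged. Passes are repeated
#' until no new flag appears, so the operation is idempotent: re-running it
#' on its own output changes nothing.
#'
#' @param series A [beat_series()].
#' @param rel_threshold Relative deviation threshold, in (0, 1). Default 0.25.
#' @param half_window Number of neighbours considered on each side
#'   (default 5, i.e. the 11-beat surrounding window less the beat itself).
#' @return The series with updated `flag` column.
#' @seealso [replace_artifacts()], [clean_beats()]
#' @export
flag_artifacts <- function(series, rel_threshold = 0.25, half_window = 5L) {
  stopifnot(inherits(series, "beat_series"))
  if (!(rel_threshold > 0 && rel_threshold < 1))
    stop("rel_threshold must lie strictly between 0 and 1")
  n <- nrow(series)
  if (n < 12L) {
    warning("fewer than 12 beats: artifact flagging skipped")
    return(series)
  }
  rr <- series$rr_ms
  flag <- series$flag
  oob <- rr <= .rr_bounds[1L] | rr >= .rr_bounds[2L]
  flag[oob & flag == "valid"] <- ifelse(rr[oob & flag == "valid"] >= .rr_bounds[2L],
                                        "missed", "false_positive")
  repeat {
    new_flag <- flag
    valid <- flag == "valid"
    for (i in which(valid)) {
      lo <- max(1L, i - half_window)
      hi <- min(n, i + half_window)
      nb <- setdiff(lo:hi, i)
      nb <- nb[valid[nb]]
      if (length(nb) < 4L) next
      med <- median(rr[nb])
      if (abs(rr[i] - med) > rel_threshold * med)
        new_flag[i] <- if (rr[i] > med) "missed" else "false_positive"
    }
    if (identical(new_flag, flag)) break
    flag <- new_flag
  }
  series$flag <- flag
  series
}

#' Replace flagged beats by linear interpolation
#'
#' Every non-valid R-R value is replaced by linear interpolation between the
#' nearest valid neighbours, in beat-index coordinates. Replaced beats are
#' re-flagged `"interpolated"`; valid beats are untouched. A non-valid run
#' touching either end of the series is replaced by the nearest valid value
#' (edge hold) with a warning.
#'
#' @param series A [beat_series()] whose flags have been computed.
#' @return The series with interpolated `rr_ms` values.
#' @export
replace_artifacts <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  bad <- series$flag != "valid"
  if (!any(bad)) return(series)
  good <- which(!bad)
  if (length(good) == 0L) stop("no valid beats left to interpolate from")
  idx <- which(bad)
  if (idx[1L] == 1L || idx[length(idx)] == nrow(series))
    warning("non-valid run touches a series edge: nearest-valid value held")
  series$rr_ms[idx] <- approx(good, series$rr_ms[good], xout = idx,
                              method = "linear", rule = 2)$y
  series$flag[idx] <- "interpolated"
  series
}

#' Clean a beat series (flag then replace)
#'
#' Convenience wrapper running [flag_artifacts()] then
#' [replace_artifacts()], and checking the physiologic R-R guard
#' (100, 3000) ms on the result.
#'
#' @inheritParams flag_artifacts
#' @return A cleaned [beat_series()] with the same number of beats.
#' @export
clean_beats <- function(series, rel_threshold = 0.25, half_window = 5L) {
  out <- replace_artifacts(flag_artifacts(series, rel_threshold, half_window))
  if (any(out$rr_ms <= .rr_bounds[1L] | out$rr_ms >= .rr_bounds[2L]))
    stop(sprintf("cleaned R-R values escape the physiologic range (%g, %g) ms",
                 .rr_bounds[1L], .rr_bounds[2L]))
  out
}

#' R-R signal on a uniform grid
#'
#' Constructor for the fixed-rate representation consumed by the windowed
#' analyses: R-R values (ms) sampled on a uniform grid.
#'
#' @param values Numeric vector of R-R values in ms.
#' @param start_time Time of the first sample, seconds.
#' @param rate Sampling rate in Hz.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, start_time, rate) {
  stopifnot(is.numeric(values), length(values) > 0, rate > 0)
  structure(list(values = as.numeric(values), start_time = start_time,
                 rate = rate), class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz from t=%.3f s (%.1f s)\n",
              length(x$values), x$rate, x$start_time,
              (length(x$values) - 1L) / x$rate))
  invisible(x)
}

#' Duration of a uniform series in seconds
#' @param x A [uniform_series()].
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.uniform_series <- function(x) (length(x$values) - 1L) / x$rate

#' Resample a beat series onto a uniform grid
#'
#' Evaluates the linear interpolant of (beat time, R-R) on the grid
#' `start_time + k / rate`, `k = 0, 1, ...`, where `start_time` is the first
#' beat time. The grid has `floor((last - first) * rate) + 1` samples.
#' Linear interpolation cannot overshoot, so every output value lies within
#' the range of the input R-R values.
#'
#' @param series A cleaned [beat_series()].
#' @param rate Target sampling rate in Hz (default 8, the conventional rate
#'   for HRV spectral analysis).
#' @return A [uniform_series()].
#' @examples
#' b <- beat_series(rr_ms = rep(500, 200))
#' u <- resample_uniform(b)
#' range(u$values)
#' @export
resample_uniform <- function(series, rate = 8) {
  stopifnot(inherits(series, "beat_series"), rate > 0)
  t <- series$time_s
  span <- t[length(t)] - t[1L]
  if (span < 1) stop("record shorter than 1 s cannot be resampled")
  nout <- floor(span * rate) + 1L
  grid <- t[1L] + (seq_len(nout) - 1L) / rate
  vals <- approx(t, series$rr_ms, xout = grid, method = "linear", rule = 2)$y
  uniform_series(vals, start_time = t[1L], rate = rate)
}
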