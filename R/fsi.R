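# The Fetal Stress Index: per-window pipeline and the 1 Hz sliding trace.

# calibration constants of the linear AUCmin -> FSI map, fitted (by the
# method's authors) on a large corpus of R-R records; taken as given
.fsi_a <- 5.1
.fsi_b <- 1.2
.fsi_scale <- 12.8

#' Mean-center and normalize one analysis window
#'
#' First stage of the index: subtract the window mean `M` (eliminating the
#' basal heart rate), then divide the deviations by their Euclidean norm
#' `S` (eliminating the overall magnitude of the variability). The result
#' is a dimensionless unit-norm vector: two windows differing only in
#' baseline or in a positive scaling of their deviations map to the same
#' normalized signal.
#'
#' @param window Numeric vector of R-R samples (ms).
#' @return A list with `M` (mean, ms), `S` (Euclidean norm of deviations,
#'   ms), `rr_norm` (unit-norm normalized samples) and `valid`. A window
#'   whose deviations have norm below `1e-6` ms (effectively constant) is
#'   marked invalid and `rr_norm` is `NULL`.
#' @export
center_and_normalize <- function(window) {
  m <- mean(window)
  dev <- window - m
  s <- sqrt(sum(dev^2))
  if (!is.finite(s) || s < 1e-6)
    return(list(M = m, S = s, rr_norm = NULL, valid = FALSE))
  list(M = m, S = s, rr_norm = dev / s, valid = TRUE)
}

#' Upper and lower envelopes of a filtered window
#'
#' Local maxima (samples strictly greater than both neighbours; a plateau
#' contributes its midpoint) define the upper envelope by linear
#' interpolation between consecutive maxima, held flat from the first/last
#' maximum out to the window edges; minima define the lower envelope
#' symmetrically. Both envelopes are then clamped so that
#' `upper >= signal >= lower` holds at every sample.
#'
#' @param x Numeric vector (the high-pass filtered, normalized window).
#' @return List with `upper`, `lower` (same length as `x`) and `valid`;
#'   a window with fewer than 2 maxima or fewer than 2 minima is invalid.
#' @export
envelopes <- function(x) {
  imax <- .local_extrema(x)
  imin <- .local_extrema(-x)
  if (length(imax) < 2L || length(imin) < 2L)
    return(list(upper = NULL, lower = NULL, valid = FALSE))
  n <- length(x)
  upper <- approx(imax, x[imax], xout = seq_len(n), method = "linear", rule = 2)$y
  lower <- approx(imin, x[imin], xout = seq_len(n), method = "linear", rule = 2)$y
  list(upper = pmax(upper, x), lower = pmin(lower, x), valid = TRUE)
}

# indices of strict local maxima; a flat run strictly above both of its
# neighbours counts once, at the run midpoint (floor)
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  i <- 2:(k - 1L)
  is_max <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  mid <- (starts[i] + ends[i]) %/% 2L
  mid[is_max]
}

#' Envelope sub-areas of one window
#'
#' The area enclosed between the upper and lower envelopes is measured on
#' four consecutive equal quarters of the window (16 s each for the default
#' 64-s window at 8 Hz) and the minimum, `auc_min`, is retained. Taking the
#' minimum of short sub-areas rather than the whole-window area makes the
#' index react quickly to transient drops in high-frequency oscillation.
#' Each sample contributes `1/rate` seconds (left Riemann rule), so the
#' four quarters carry identical measure and an envelope gap that is
#' constant at `c` yields `A_k = 16 * c` exactly.
#'
#' @param upper,lower Envelope samples from [envelopes()].
#' @param rate Sampling rate in Hz (default 8).
#' @param k Number of sub-areas (default 4).
#' @return List with `areas` (numeric vector of length `k`, in
#'   normalized-unit seconds) and `auc_min`.
#' @export
subareas <- function(upper, lower, rate = 8, k = 4L) {
  n <- length(upper)
  stopifnot(length(lower) == n, n %% k == 0L)
  gap <- upper - lower
  if (any(gap < -1e-12)) stop("upper envelope below lower envelope")
  qlen <- n %/% k
  areas <- vapply(seq_len(k), function(q) {
    sum(gap[((q - 1L) * qlen + 1L):(q * qlen)]) / rate
  }, numeric(1))
  list(areas = areas, auc_min = min(areas))
}

#' Map the minimum envelope sub-area to the 0-100 index
#'
#' `FSI = 100 * (5.1 * auc_min + 1.2) / 12.8`, clipped to `[0, 100]`. The
#' linear map is not intrinsically bounded; clipping enforces the index's
#' stated range. The constants were calibrated by the method's authors so
#' that the number tracks the visual aspect of the filtered R-R series.
#'
#' @param auc_min Minimum envelope sub-area, normalized-unit seconds, >= 0.
#' @return The index value in `[0, 100]`.
#' @examples
#' fsi_from_auc(0)    # 9.375: the map's intercept
#' fsi_from_auc(3)    # clipped at 100
#' @export
fsi_from_auc <- function(auc_min) {
  if (any(auc_min < 0)) stop("auc_min must be non-negative")
  raw <- 100 * (.fsi_a * auc_min + .fsi_b) / .fsi_scale
  pmin(pmax(raw, 0), 100)
}

#' Compute the Fetal Stress Index for one 64-s window
#'
#' Runs the full per-window pipeline: mean-centering and Euclidean
#' normalization, Daubechies 4-tap wavelet high-pass, envelope extraction,
#' sub-area measurement and the linear index map. All intermediates are
#' returned so each stage can be inspected (or plotted).
#'
#' @param window Numeric vector of R-R samples (ms). Length must be a
#'   power of two; the canonical window is 512 samples = 64 s at 8 Hz.
#' @param rate Sampling rate in Hz (default 8).
#' @param levels Wavelet decomposition depth (default 5 -> dyadic cutoff
#'   0.125 Hz at 8 Hz).
#' @return An object of class `fsi_window`: list with `M`, `S`, `rr_norm`,
#'   `filtered`, `upper_env`, `lower_env`, `areas` (A1..A4), `auc_min`,
#'   `fsi`, `valid` and `reason` (why a window was invalidated, or `NA`).
#' @examples
#' t <- seq(0, by = 1 / 8, length.out = 512)
#' w <- fsi_window(400 + 10 * sin(2 * pi * 0.5 * t))
#' w$fsi
#' @export
fsi_window <- function(window, rate = 8, levels = 5L) {
  out <- list(M = NA_real_, S = NA_real_, rr_norm = NULL, filtered = NULL,
              upper_env = NULL, lower_env = NULL, areas = rep(NA_real_, 4L),
              auc_min = NA_real_, fsi = NA_real_, valid = FALSE,
              reason = NA_character_)
  class(out) <- "fsi_window"
  cn <- center_and_normalize(window)
  out$M <- cn$M; out$S <- cn$S
  if (!cn$valid) { out$reason <- "constant window"; return(out) }
  out$rr_norm <- cn$rr_norm
  out$filtered <- highpass_wavelet(cn$rr_norm, levels)
  env <- envelopes(out$filtered)
  if (!env$valid) { out$reason <- "too few envelope extrema"; return(out) }
  out$upper_env <- env$upper; out$lower_env <- env$lower
  sa <- subareas(env$upper, env$lower, rate = rate)
  out$areas <- sa$areas; out$auc_min <- sa$auc_min
  out$fsi <- fsi_from_auc(sa$auc_min)
  out$valid <- TRUE
  out
}

#' @export
print.fsi_window <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<fsi_window> FSI %.2f (M %.1f ms, S %.2f ms, AUCmin %.4f; A = %s)\n",
                x$fsi, x$M, x$S, x$auc_min,
                paste(sprintf("%.3f", x$areas), collapse = ", ")))
  else
    cat(sprintf("<fsi_window> invalid (%s)\n", x$reason))
  invisible(x)
}

#' Sliding-window index trace
#'
#' `fsi_trace()` computes one [fsi_window()] per 1-s step of a 64-s window
#' sliding over the uniform 8 Hz R-R signal, yielding a 1 Hz time series of
#' the index. Timestamps are window centers; invalid windows carry `NA`,
#' never a fabricated number.
#'
#' @param signal A [uniform_series()] of duration >= 64 s.
#' @param window_s Window length in seconds (default 64).
#' @param step_s Step between window starts in seconds (default 1).
#' @param levels Wavelet depth passed to [fsi_window()].
#' @return An [index_trace()] with `floor(duration - window_s) + 1` points.
#' @export
fsi_trace <- function(signal, window_s = 64, step_s = 1, levels = 5L) {
  stopifnot(inherits(signal, "uniform_series"))
  rate <- signal$rate
  nwin <- as.integer(round(window_s * rate))
  if (duration(signal) < window_s)
    stop(sprintf("signal duration %.1f s is shorter than the %g s window",
                 duration(signal), window_s))
  starts <- .window_starts(length(signal$values), nwin, rate, step_s)
  vals <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    w <- fsi_window(signal$values[starts[i]:(starts[i] + nwin - 1L)],
                    rate = rate, levels = levels)
    if (w$valid) vals[i] <- w$fsi
  }
  times <- signal$start_time + (starts - 1L) / rate + window_s / 2
  index_trace(times, vals, name = "fsi")
}

# 1-based sample indices of window starts for an n-sample signal
.window_starts <- function(n, nwin, rate, step_s) {
  step <- as.integer(round(step_s * rate))
  last <- n - nwin + 1L
  if (last < 1L) stop("signal shorter than one window")
  seq(1L, last, by = step)
}

#' A 1 Hz time series of an index
#'
#' Container for the sliding-window traces produced by [fsi_trace()] and
#' [spectral_trace()]: strictly increasing window-center timestamps with an
#' exact 1-s step, values, and a validity mask (`NA` values are invalid
#' windows).
#'
#' @param times Window-center timestamps, seconds.
#' @param values Index values (`NA` = invalid window).
#' @param name Index name (e.g. `"fsi"`, `"hf"`).
#' @return An object of class `index_trace`.
#' @export
index_trace <- function(times, values, name = "index") {
  stopifnot(length(times) == length(values))
  if (length(times) > 1L && any(abs(diff(times) - diff(times)[1L]) > 1e-9))
    stop("index_trace timestamps must be evenly spaced")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 valid = !is.na(values), name = name),
            class = "index_trace")
}

#' @export
print.index_trace <- function(x, ...) {
  cat(sprintf("<index_trace '%s'> %d points, %.0f-%.0f s, %d valid\n",
              x$name, length(x$times), min(x$times), max(x$times),
              sum(x$valid)))
  invisible(x)
}

#' Mean of an index over an analysis period
#'
#' Arithmetic mean of the valid trace values whose window-center timestamp
#' lies in `[t0, t1)`. The blockade analyses use two such 5-minute periods,
#' one well before and one well after the injection; the transition itself
#' is never averaged over.
#'
#' @param trace An [index_trace()].
#' @param t0,t1 Period bounds in seconds (half-open interval).
#' @param min_valid Minimum fraction of valid windows required (default
#'   0.5); below it the result is `NA` with a warning.
#' @return The period mean, or `NA` if too few windows are valid.
#' @export
period_mean <- function(trace, t0, t1, min_valid = 0.5) {
  stopifnot(inherits(trace, "index_trace"), t1 > t0)
  span <- range(trace$times)
  if (t0 > span[2L] || t1 <= span[1L])
    stop(sprintf("period [%g, %g) lies outside the trace span [%g, %g]",
                 t0, t1, span[1L], span[2L]))
  sel <- trace$times >= t0 & trace$times < t1
  if (!any(sel)) stop("no trace points in the requested period")
  v <- trace$values[sel]
  if (mean(!is.na(v)) < min_valid) {
    warning(sprintf("only %.0f%% of windows in [%g, %g) are valid; returning NA",
                    100 * mean(!is.na(v)), t0, t1))
    return(NA_real_)
  }
  mean(v, na.rm = TRUE)
}
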