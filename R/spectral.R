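# Classic HRV comparators: RMSSD and FFT band powers.

#' Root mean square of successive R-R differences
#'
#' Classic time-domain vagal marker, computed on the cleaned beat-to-beat
#' intervals (never on the resampled signal, whose interpolation distorts
#' successive differences).
#'
#' @param series A [beat_series()].
#' @param t0,t1 Optional interval in seconds; beats with
#'   `t0 <= time < t1` are used. Defaults to the whole record.
#' @return RMSSD in ms.
#' @examples
#' rmssd(beat_series(rr_ms = c(1000, 1010, 990)))  # 15.8114
#' @export
rmssd <- function(series, t0 = -Inf, t1 = Inf) {
  stopifnot(inherits(series, "beat_series"))
  rr <- series$rr_ms[series$time_s >= t0 & series$time_s < t1]
  if (length(rr) < 3L)
    stop("RMSSD needs at least 3 beats in the interval (got ", length(rr), ")")
  sqrt(mean(diff(rr)^2))
}

#' HRV spectral bands
#'
#' The conventional band edges: very low frequency 0 - 0.04 Hz
#' (thermoregulatory/endocrine), low frequency 0.04 - 0.15 Hz (mixed
#' sympathetic + parasympathetic, baroreflex), high frequency above
#' 0.15 Hz (parasympathetic only). The upper HF edge is not standardized
#' for fetal work; the default runs to the 4 Hz Nyquist of the 8 Hz grid.
#'
#' @param hf_upper Upper edge of the HF band in Hz (default 4).
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
hrv_bands <- function(hf_upper = 4) {
  stopifnot(hf_upper > 0.15)
  list(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, hf_upper))
}

#' Band powers of one spectral analysis window
#'
#' Mean-centers the window, applies a Bartlett (triangular) taper, takes
#' the FFT and integrates the one-sided power spectrum over the VLF, LF and
#' HF bands (half-open intervals `[lo, hi)`, DC bin excluded). Powers are
#' normalized by the taper power `sum(w^2)` so that their grand total
#' equals `sum((w*x)^2) / sum(w^2)`, an unbiased estimate of the signal
#' variance in ms^2 for broadband signals.
#'
#' @param window Numeric vector of R-R samples (ms); the canonical window
#'   is 2048 samples = 256 s at 8 Hz.
#' @param rate Sampling rate in Hz (default 8).
#' @param bands Band edges from [hrv_bands()].
#' @return List with `vlf`, `lf`, `hf` (ms^2), `nhf = hf / (hf + lf)`
#'   (`NA` when `hf + lf` is zero), and `total` (sum of all one-sided
#'   powers excluding DC).
#' @export
band_spectrum <- function(window, rate = 8, bands = hrv_bands()) {
  n <- length(window)
  if (n < 8L) stop("spectral window too short")
  w <- .bartlett(n)
  y <- w * (window - mean(window))
  p2 <- Mod(fft(y))^2 / (n * sum(w^2))   # two-sided power per bin
  half <- n %/% 2L
  freq <- (0:half) * rate / n
  pow <- p2[1:(half + 1L)]
  fold <- 2:(if (n %% 2L == 0L) half else half + 1L)  # bins with a mirror
  pow[fold] <- 2 * pow[fold]
  inband <- function(b) sum(pow[freq >= b[1L] & freq < b[2L] & freq > 0])
  out <- lapply(bands, inband)
  out$nhf <- if ((out$hf + out$lf) > 0) out$hf / (out$hf + out$lf) else NA_real_
  out$total <- sum(pow[freq > 0])
  out
}

.bartlett <- function(n) {
  k <- seq_len(n) - 1L
  1 - abs(2 * k / (n - 1L) - 1)
}

#' Sliding spectral analysis
#'
#' Slides a 256-s mean-centered, Bartlett-tapered FFT window over the 8 Hz
#' R-R signal with a 1-s step, producing 1 Hz traces of the VLF, LF, HF,
#' normalized HF and total powers. Timestamps are window centers.
#'
#' @param signal A [uniform_series()] of duration >= `window_s`.
#' @param window_s Spectral window length in seconds (default 256).
#' @param step_s Step between window starts (default 1 s).
#' @param bands Band edges from [hrv_bands()].
#' @return An object of class `spectral_trace`: a data frame with columns
#'   `time_s`, `vlf`, `lf`, `hf`, `nhf`, `total`. Use [band_trace()] to
#'   extract a single band as an [index_trace()].
#' @export
spectral_trace <- function(signal, window_s = 256, step_s = 1,
                           bands = hrv_bands()) {
  stopifnot(inherits(signal, "uniform_series"))
  rate <- signal$rate
  nwin <- as.integer(round(window_s * rate))
  if (duration(signal) < window_s)
    stop(sprintf("signal duration %.1f s is shorter than the %g s spectral window",
                 duration(signal), window_s))
  starts <- .window_starts(length(signal$values), nwin, rate, step_s)
  res <- matrix(NA_real_, nrow = length(starts), ncol = 5L,
                dimnames = list(NULL, c("vlf", "lf", "hf", "nhf", "total")))
  for (i in seq_along(starts)) {
    bs <- band_spectrum(signal$values[starts[i]:(starts[i] + nwin - 1L)],
                        rate = rate, bands = bands)
    res[i, ] <- c(bs$vlf, bs$lf, bs$hf, bs$nhf, bs$total)
  }
  times <- signal$start_time + (starts - 1L) / rate + window_s / 2
  structure(data.frame(time_s = times, res),
            class = c("spectral_trace", "data.frame"))
}

#' Extract one band of a spectral trace as an index trace
#'
#' @param x A [spectral_trace()].
#' @param band One of `"vlf"`, `"lf"`, `"hf"`, `"nhf"`, `"total"`.
#' @return An [index_trace()].
#' @export
band_trace <- function(x, band = c("hf", "lf", "vlf", "nhf", "total")) {
  band <- match.arg(band)
  stopifnot(inherits(x, "spectral_trace"))
  index_trace(x$time_s, x[[band]], name = band)
}
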