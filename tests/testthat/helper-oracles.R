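# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package internals.

# running-median artifact rule: for beat i, median RR of the valid beats
# within hw positions on either side (self excluded); flag if relative
# deviation exceeds thr
oracle_flag <- function(rr, valid, thr = 0.25, hw = 5L) {
  n <- length(rr)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    nb <- c()
    for (j in max(1, i - hw):min(n, i + hw))
      if (j != i && valid[j]) nb <- c(nb, rr[j])
    if (length(nb) < 4) next
    m <- sort(nb)[ceiling(length(nb) / 2)]
    if (length(nb) %% 2 == 0)
      m <- (sort(nb)[length(nb) / 2] + sort(nb)[length(nb) / 2 + 1]) / 2
    if (abs(rr[i] - m) > thr * m) out[i] <- TRUE
  }
  out
}

# piecewise-linear interpolation of flagged beats in index coordinates
oracle_interp <- function(rr, bad) {
  n <- length(rr)
  out <- rr
  for (i in which(bad)) {
    lo <- i; while (lo >= 1 && bad[lo]) lo <- lo - 1
    hi <- i; while (hi <= n && bad[hi]) hi <- hi + 1
    if (lo < 1 && hi > n) stop("no valid beats")
    if (lo < 1) out[i] <- rr[hi]
    else if (hi > n) out[i] <- rr[lo]
    else out[i] <- rr[lo] + (rr[hi] - rr[lo]) * (i - lo) / (hi - lo)
  }
  out
}

# evaluate the piecewise-linear interpolant of (xs, ys) at x
oracle_lininterp <- function(xs, ys, x) {
  sapply(x, function(xx) {
    if (xx <= xs[1]) return(ys[1])
    if (xx >= xs[length(xs)]) return(ys[length(ys)])
    k <- max(which(xs <= xx))
    if (xs[k] == xx) return(ys[k])
    ys[k] + (ys[k + 1] - ys[k]) * (xx - xs[k]) / (xs[k + 1] - xs[k])
  })
}

# quarter areas by explicit per-sample accumulation (left Riemann, 1/rate
# seconds per sample)
oracle_areas <- function(gap, rate = 8, k = 4) {
  qlen <- length(gap) / k
  out <- numeric(k)
  for (q in 1:k) {
    acc <- 0
    for (j in ((q - 1) * qlen + 1):(q * qlen)) acc <- acc + gap[j] / rate
    out[q] <- acc
  }
  out
}

# two-line RMSSD
oracle_rmssd <- function(rr) sqrt(mean(diff(rr)^2))

# exact two-sided signed-rank p by explicit loop over all 2^n sign patterns
oracle_wilcoxon_exact <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    ws[m + 1] <- sum(r[bits == 1L])
  }
  min(1, 2 * min(mean(ws <= w_obs + 1e-12), mean(ws >= w_obs - 1e-12)))
}

# sorted-interpolation quantile (R type 7 definition, written out longhand)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# FFT energy ratio: fraction of signal energy the filter retained
oracle_energy_ratio <- function(filtered, original) {
  sum(Mod(fft(filtered))^2) / sum(Mod(fft(original))^2)
}

# fixture builders -----------------------------------------------------------

constant_beats <- function(n = 300, rr = 400) beat_series(rr_ms = rep(rr, n))

sine_window <- function(freq, amp = 10, n = 512, rate = 8, base = 400,
                        phase = 0) {
  t <- (seq_len(n) - 1) / rate
  base + amp * sin(2 * pi * freq * t + phase)
}

sine_signal <- function(freq, amp = 10, dur = 300, rate = 8, base = 400) {
  n <- dur * rate + 1
  t <- (seq_len(n) - 1) / rate
  uniform_series(base + amp * sin(2 * pi * freq * t), start_time = 0,
                 rate = rate)
}
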