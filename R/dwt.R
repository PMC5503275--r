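# Discrete wavelet transform with the Daubechies 4-tap (2 vanishing
# moments) filter pair, symmetric half-sample boundary extension, and
# exact reconstruction. Implemented here because the dyadic high-pass is
# the heart of the index; the filter bank is verified against a
# perfect-reconstruction property in the test suite.

.db2_filters <- local({
  s <- sqrt(3)
  rec_lo <- c(1 + s, 3 + s, 3 - s, 1 - s) / (4 * sqrt(2))
  dec_lo <- rev(rec_lo)
  dec_hi <- rec_lo * c(1, -1, 1, -1)
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi,
       len = 4L)
})

.sym_ext <- function(x, k) {
  n <- length(x)
  c(x[k:1], x, x[n:(n - k + 1L)])
}

.conv_full <- function(a, b) convolve(a, rev(b), type = "open")

# one analysis step: returns approximation and detail coefficients,
# each of length floor((n + 3) / 2)
.dwt_step <- function(x) {
  f <- .db2_filters
  ext <- .sym_ext(x, f$len - 1L)
  nc <- (length(x) + f$len - 1L) %/% 2L
  idx <- seq(5L, by = 2L, length.out = nc)
  list(a = .conv_full(ext, f$dec_lo)[idx],
       d = .conv_full(ext, f$dec_hi)[idx])
}

# one synthesis step back to length n (inverts .dwt_step exactly)
.idwt_step <- function(a, d, n) {
  f <- .db2_filters
  up <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, by = 2L, length.out = length(cf))] <- cf
    u
  }
  r <- .conv_full(up(a), f$rec_lo) + .conv_full(up(d), f$rec_hi)
  r[3:(2L + n)]
}

#' Multi-level Daubechies 4-tap wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus a final
#' approximation, using the orthogonal Daubechies wavelet with 4 filter
#' coefficients and symmetric (half-sample) boundary extension.
#' [wavelet_reconstruct()] inverts the decomposition exactly (to floating
#' point); the pair is the basis of [highpass_wavelet()].
#'
#' @param x Numeric signal.
#' @param levels Number of decomposition levels (default 5).
#' @return A list with elements `details` (list of detail coefficient
#'   vectors, finest first), `approx` (final approximation coefficients)
#'   and `lengths` (original length at each level, needed for synthesis).
#' @export
wavelet_decompose <- function(x, levels = 5L) {
  stopifnot(is.numeric(x), levels >= 1L)
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    st <- .dwt_step(cur)
    details[[j]] <- st$d
    cur <- st$a
  }
  list(details = details, approx = cur, lengths = lens)
}

#' @rdname wavelet_decompose
#' @param w A decomposition from [wavelet_decompose()].
#' @export
wavelet_reconstruct <- function(w) {
  cur <- w$approx
  for (j in rev(seq_along(w$details)))
    cur <- .idwt_step(cur, w$details[[j]], w$lengths[j])
  cur
}

#' Dyadic wavelet high-pass filter
#'
#' High-pass filters a signal by zeroing the final approximation band of a
#' `levels`-deep Daubechies 4-tap decomposition and reconstructing. At a
#' sampling rate of 8 Hz and 5 levels the approximation band covers
#' 0 - 0.125 Hz, so the reconstruction retains oscillations above the
#' nearest realizable dyadic cutoff to the 0.15 Hz high-frequency band
#' edge (pass band roughly 0.125 - 4 Hz). Deterministic: no randomness,
#' no data-dependent choices.
#'
#' @param x Numeric signal whose length is a power of two.
#' @param levels Decomposition depth (default 5; each extra level halves
#'   the cutoff).
#' @return The filtered signal, same length as `x`.
#' @examples
#' highpass_wavelet(rep(1, 64))  # DC is removed entirely
#' @export
highpass_wavelet <- function(x, levels = 5L) {
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("signal length must be a power of two (got ", n, ")")
  w <- wavelet_decompose(x, levels)
  w$approx <- numeric(length(w$approx))
  wavelet_reconstruct(w)
}
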