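# Static plotting helpers (base graphics; deliberately minimal).

#' Plot one analysis window with its envelopes
#'
#' Shows the normalized, high-pass filtered window together with its upper
#' and lower envelopes and the four sub-area boundaries.
#'
#' @param x An [fsi_window()] result.
#' @param rate Sampling rate used to label the time axis (default 8 Hz).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fsi_window <- function(x, rate = 8, ...) {
  if (!x$valid) stop("cannot plot an invalid window (", x$reason, ")")
  n <- length(x$filtered)
  t <- (seq_len(n) - 1L) / rate
  graphics::plot(t, x$filtered, type = "l", xlab = "time in window (s)",
                 ylab = "normalized, filtered R-R", ...)
  graphics::lines(t, x$upper_env, col = "grey40", lty = 2)
  graphics::lines(t, x$lower_env, col = "grey40", lty = 2)
  graphics::abline(v = t[n] * (1:3) / 4, col = "grey80")
  graphics::mtext(sprintf("FSI %.1f (AUCmin %.3f)", x$fsi, x$auc_min))
  invisible(x)
}

#' Plot an index trace
#'
#' @param x An [index_trace()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.index_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = x$name, ...)
  invisible(x)
}
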