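#' Beat-to-beat R-R interval series
#'
#' A `beat_series` is the package's container for an irregular beat-to-beat
#' record: one row per detected R wave, holding the beat time (seconds from
#' record start), the R-R interval that ended at that beat (ms), and a
#' per-beat quality flag.
#'
#' @param time_s Numeric vector of beat times in seconds, strictly
#'   increasing. May be `NULL`, in which case times are reconstructed as the
#'   cumulative sum of `rr_ms` (the first beat falls at `rr_ms[1]/1000` s).
#' @param rr_ms Numeric vector of R-R intervals in milliseconds, all > 0.
#' @param flag Character vector of per-beat quality flags, one of
#'   `"valid"`, `"missed"`, `"false_positive"`, `"ectopic"`,
#'   `"interpolated"`. Recycled if length 1.
#'
#' @return An object of class `beat_series`: a data frame with columns
#'   `time_s`, `rr_ms`, `flag`.
#' @examples
#' b <- beat_series(rr_ms = rep(400, 10))
#' b$time_s[1:3]
#' @export
beat_series <- function(time_s = NULL, rr_ms, flag = "valid") {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) == 0L) stop("beat series must contain at least one beat")
  if (anyNA(rr_ms) || any(!is.finite(rr_ms))) stop("rr_ms must be finite")
  if (any(rr_ms <= 0)) {
    bad <- which(rr_ms <= 0)[1L]
    stop(sprintf("rr_ms must be positive (beat %d has rr = %g ms)", bad, rr_ms[bad]))
  }
  if (is.null(time_s)) {
    time_s <- cumsum(rr_ms) / 1000
  } else {
    time_s <- as.numeric(time_s)
    if (length(time_s) != length(rr_ms)) stop("time_s and rr_ms lengths differ")
    if (any(diff(time_s) <= 0)) stop("beat times must be strictly increasing")
  }
  flag <- rep_len(as.character(flag), length(rr_ms))
  bad_flag <- setdiff(unique(flag), beat_flags())
  if (length(bad_flag)) stop("unknown beat flag(s): ", paste(bad_flag, collapse = ", "))
  structure(
    data.frame(time_s = time_s, rr_ms = rr_ms, flag = flag,
               stringsAsFactors = FALSE),
    class = c("beat_series", "data.frame")
  )
}

#' @rdname beat_series
#' @export
beat_flags <- function() c("valid", "missed", "false_positive", "ectopic", "interpolated")

#' @export
print.beat_series <- function(x, ...) {
  n <- nrow(x)
  dur <- x$time_s[n] - x$time_s[1L]
  nbad <- sum(x$flag != "valid")
  cat(sprintf("<beat_series> %d beats over %.1f s (mean RR %.1f ms, %d non-valid)\n",
              n, dur, mean(x$rr_ms), nbad))
  invisible(x)
}

# physiologic R-R guard applied after cleaning
.rr_bounds <- c(100, 3000)

#' Read and write R-R interval files
#'
#' `read_rr()` accepts either a delimited file (comma or tab) with a header
#' `time_s,rr_ms[,flag]`, or a headerless single column of consecutive R-R
#' intervals in ms (beat times reconstructed by cumulative sum).
#' `write_rr()` writes the same dialect with flags as lowercase strings;
#' the round trip is lossless to well below 1e-9 ms.
#'
#' @param path Path to the file.
#' @param series A [beat_series()].
#' @param sep Field separator for writing (default comma).
#' @return `read_rr()` returns a [beat_series()]; `write_rr()` returns
#'   `path` invisibly.
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty input file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (grepl("time_s", first, fixed = TRUE)) {
    df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
    if (!all(c("time_s", "rr_ms") %in% names(df)))
      stop("header must provide columns time_s and rr_ms: ", path)
    .check_numeric_column(df$rr_ms, "rr_ms", path)
    .check_numeric_column(df$time_s, "time_s", path)
    flag <- if ("flag" %in% names(df)) tolower(df$flag) else "valid"
    beat_series(time_s = df$time_s, rr_ms = df$rr_ms, flag = flag)
  } else {
    df <- read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE)
    .check_numeric_column(df[[1L]], "rr_ms", path)
    beat_series(rr_ms = df[[1L]])
  }
}

.check_numeric_column <- function(x, name, path) {
  if (!is.numeric(x)) stop(sprintf("column %s in %s is not numeric", name, path))
  bad <- which(!is.finite(x) | (name == "rr_ms" & x <= 0))
  if (length(bad))
    stop(sprintf("invalid %s at data row %d of %s (value %s)",
                 name, bad[1L], path, format(x[bad[1L]])))
}

#' @rdname read_rr
#' @export
write_rr <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "beat_series"))
  df <- as.data.frame(series)
  df$flag <- tolower(df$flag)
  # full double precision so write/read round trips are exact
  df$time_s <- sprintf("%.12g", df$time_s)
  df$rr_ms <- sprintf("%.12g", df$rr_ms)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
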