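# Paired before/after statistics for small autonomic-blockade cohorts.

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the paired differences `after - before`.
#' Zero differences are dropped (the usual Wilcoxon convention); ties in
#' the absolute differences receive average ranks. For `n <= exact_max`
#' non-zero differences the exact p-value is obtained by full enumeration
#' of all `2^n` sign assignments; the normal approximation (no continuity
#' correction, tie-corrected variance) is always reported alongside, since
#' common statistical software prints the asymptotic value even at small n.
#'
#' @param before,after Paired numeric vectors.
#' @param exact_max Largest n for which the exact enumeration is used as
#'   the headline p-value (default 15).
#' @return List with `statistic` (W+, sum of positive ranks), `n` (non-zero
#'   pairs), `n_zero` (dropped zero differences), `p_exact` (`NA` when
#'   n > `exact_max`), `p_asymptotic`, `p_value` (exact when available,
#'   else asymptotic) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10, 11), c(4, 3, 5, 6, 2, 8, 9))
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 15L) {
  stopifnot(length(before) == length(after))
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero: p = 1")
    return(list(statistic = 0, n = 0L, n_zero = n_zero, p_exact = 1,
                p_asymptotic = 1, p_value = 1, method = "degenerate"))
  }
  if (n < 3L) stop("need at least 3 non-zero differences (got ", n, ")")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  # exact: distribution of W+ under all 2^n sign flips
  p_exact <- NA_real_
  if (n <= exact_max) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p_exact <- min(1, 2 * min(mean(sums <= w + 1e-12), mean(sums >= w - 1e-12)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu) / sqrt(sig2)
  p_asym <- 2 * pnorm(-abs(z))
  list(statistic = w, n = n, n_zero = n_zero, p_exact = p_exact,
       p_asymptotic = p_asym,
       p_value = if (!is.na(p_exact)) p_exact else p_asym,
       method = if (!is.na(p_exact)) "exact" else "asymptotic")
}

#' Paired Cohen's d (d_z)
#'
#' Effect size for a paired design: the mean difference divided by the
#' standard deviation of the differences,
#' `d = mean(D) / sqrt(SS_D / (n - 1))` with `SS_D` the sum of squared
#' deviations of the differences from their mean. This is the d_z variant,
#' not the classical pooled-SD d; it is what blockade studies report for
#' before/after contrasts.
#'
#' @param before,after Paired numeric vectors; incomplete pairs dropped.
#' @return List with `d`, `d_bar` (mean difference), `ss_d`, `n` and
#'   `degenerate` (`TRUE` when all differences are equal and non-zero, in
#'   which case `d` is signed infinity).
#' @examples
#' cohens_d_paired(c(5, 6, 7), c(3, 3, 3))$d  # -3
#' @export
cohens_d_paired <- function(before, after) {
  stopifnot(length(before) == length(after))
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  d_bar <- mean(d)
  ss_d <- sum((d - d_bar)^2)
  if (ss_d == 0) {
    if (d_bar == 0)
      return(list(d = 0, d_bar = 0, ss_d = 0, n = n, degenerate = FALSE))
    return(list(d = sign(d_bar) * Inf, d_bar = d_bar, ss_d = 0, n = n,
                degenerate = TRUE))
  }
  list(d = d_bar / sqrt(ss_d / (n - 1)), d_bar = d_bar, ss_d = ss_d, n = n,
       degenerate = FALSE)
}

#' Percent coefficient of variation
#'
#' `%CV = 100 * SD / M` with the sample standard deviation (n-1
#' denominator). The inter-subject dispersion measure used to compare
#' index thresholds across animals. For a negative mean the magnitude
#' `|M|` is used and a message is emitted (the indices this package
#' computes are positive in practice).
#'
#' @param values Numeric vector, `n >= 2`, mean non-zero.
#' @return The coefficient of variation in percent.
#' @examples
#' cv_percent(c(45, 50, 55))
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("%CV undefined for zero mean")
  if (m < 0) message("negative mean: %CV computed against |mean|")
  100 * sd(values) / abs(m)
}

#' Median and quartile summary
#'
#' `median (Q1-Q3)` in the convention of small-cohort physiology tables.
#' Quartiles use linear interpolation of order statistics (R's default
#' type 7); the convention is configurable because different software
#' families interpolate differently and quartiles of n = 7 samples are
#' sensitive to it.
#'
#' @param values Numeric vector, `n >= 1`.
#' @param type Quantile type passed to [stats::quantile()] (default 7,
#'   linear interpolation; SPSS-style is type 6).
#' @return List with `median`, `q1`, `q3`, `n` and a preformatted `label`
#'   like `"3 (2-4)"`.
#' @export
summarize_quartiles <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least 1 value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  list(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(values),
       label = sprintf("%.4g (%.4g-%.4g)", q[2L], q[1L], q[3L]))
}

#' Paired before/after comparison of one index
#'
#' Bundles the complete statistical readout of a before/after contrast for
#' one index across subjects: median (Q1-Q3) summaries, %CV per period,
#' Wilcoxon p-values and paired Cohen's d. Effect size is reported as a
#' magnitude carrying the sign of the mean difference.
#'
#' @param before,after Per-subject index values (same order); incomplete
#'   pairs are dropped and counted.
#' @param index Name of the index (e.g. `"fsi"`).
#' @param quantile_type Quartile convention (see [summarize_quartiles()]).
#' @return An object of class `paired_comparison`.
#' @export
paired_comparison <- function(before, after, index = "index",
                              quantile_type = 7) {
  stopifnot(length(before) == length(after))
  ok <- !is.na(before) & !is.na(after)
  n_dropped <- sum(!ok)
  b <- before[ok]; a <- after[ok]
  wt <- wilcoxon_signed_rank(b, a)
  cd <- cohens_d_paired(b, a)
  structure(list(
    index = index, n = length(b), n_dropped = n_dropped,
    subjects = which(ok), before = b, after = a, diffs = a - b,
    d_bar = cd$d_bar, ss_d = cd$ss_d,
    summary_before = summarize_quartiles(b, type = quantile_type),
    summary_after = summarize_quartiles(a, type = quantile_type),
    cv_before = cv_percent(b), cv_after = cv_percent(a),
    p_value = wt$p_value, p_exact = wt$p_exact,
    p_asymptotic = wt$p_asymptotic, statistic = wt$statistic,
    cohens_d = cd$d, degenerate = cd$degenerate
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison '%s'> n=%d\n", x$index, x$n))
  cat(sprintf("  before %s  (%%CV %.1f)\n", x$summary_before$label, x$cv_before))
  cat(sprintf("  after  %s  (%%CV %.1f)\n", x$summary_after$label, x$cv_after))
  cat(sprintf("  Wilcoxon p = %.4g (exact %.4g / asymptotic %.4g), Cohen's d = %.2f\n",
              x$p_value, x$p_exact, x$p_asymptotic, x$cohens_d))
  invisible(x)
}

#' Tabulate paired comparisons
#'
#' Renders a list of [paired_comparison()] objects as the canonical
#' blockade-study table: one row per index with columns Before, %CV
#' before, After, %CV after, p, and Effect size (|d| with the sign of the
#' mean difference).
#'
#' @param comparisons A list of [paired_comparison()] objects.
#' @return A data frame with one row per index.
#' @export
comparison_table <- function(comparisons) {
  stopifnot(length(comparisons) > 0)
  rows <- lapply(comparisons, function(cc) {
    data.frame(
      index = cc$index,
      before = cc$summary_before$label,
      cv_before = round(cc$cv_before, 1),
      after = cc$summary_after$label,
      cv_after = round(cc$cv_after, 1),
      p = signif(cc$p_value, 3),
      effect_size = round(abs(cc$cohens_d) * sign(cc$d_bar + (cc$d_bar == 0)), 2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Markdown rendering of a comparison table
#' @param tab A data frame from [comparison_table()].
#' @return Character vector of markdown lines.
#' @export
comparison_markdown <- function(tab) {
  hdr <- c("| Index | Before | %CV before | After | %CV after | p | Effect size |",
           "|---|---|---|---|---|---|---|")
  rows <- apply(tab, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, rows)
}
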