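# Seeded generator of fetal-like R-R series and the in-silico
# autonomic-blockade experiment harness.

#' Scenario configuration for the R-R simulator
#'
#' Describes one simulated blockade experiment: fetal-like baseline
#' (basal heart rate around 150-190 bpm), sinusoidal low-frequency and
#' high-frequency autonomic modulation of the instantaneous heart period,
#' per-beat measurement jitter, detection artifacts, slow behavioural-state
#' drift of the modulation amplitudes, between-subject variation, and an
#' optional drug given mid-record.
#'
#' Drug effects (applied smoothly over a 30-s transition after
#' `drug_time`): atropine suppresses the HF amplitude (x0.25) and raises
#' the basal heart rate (x1.22, emulating the ~156 to ~190 bpm rise of
#' vagal blockade); propranolol suppresses the LF amplitude (x0.35) and
#' lowers the heart rate (x0.91, ~161 to ~147 bpm).
#'
#' @param duration Record length in seconds (default 1500 = 25 min).
#' @param basal_hr Basal fetal heart rate, bpm (default 156).
#' @param a_lf,a_hf LF and HF modulation amplitudes, ms (defaults 7 and
#'   10; sinusoid powers a^2/2 of the order of the LF/HF band powers seen
#'   in fetal sheep).
#' @param a_vlf Standard deviation of the very-low-frequency wander, ms
#'   (default 12): a smooth Gaussian process (25-s knots, band below about
#'   0.04 Hz) emulating the slow thermoregulatory/endocrine drift that
#'   dominates total fetal HRV power.
#' @param f_lf,f_hf Modulation frequencies, Hz. `f_lf` must lie in
#'   [0.04, 0.15), `f_hf` at or above 0.15 (defaults 0.08 and 0.5).
#' @param jitter_sd Per-beat Gaussian measurement noise, ms (default 3).
#' @param artifact_rate Per-beat probability of a detection artifact
#'   (missed beat or spurious detection), capped at 0.05 (default 0.01).
#' @param amp_mod_sd Relative SD of the slow lognormal drift of the
#'   modulation amplitudes (60-s knots, default 0.25), emulating fetal
#'   behavioural-state nonstationarity.
#' @param n_subjects Cohort size (default 7).
#' @param subject_sd Relative between-subject SD applied to basal heart
#'   rate and modulation amplitudes (default 0.25, which reproduces the
#'   inter-subject dispersion regime reported for instrumented fetal
#'   sheep: band-power coefficients of variation of tens of percent).
#' @param drug One of `"none"`, `"atropine"`, `"propranolol"`.
#' @param drug_time Injection time in seconds (default `duration / 2`).
#' @param seed Master seed; identical (config, seed) pairs generate
#'   bit-identical cohorts.
#' @return A validated object of class `scenario_config`.
#' @export
scenario_config <- function(duration = 1500, basal_hr = 156,
                            a_lf = 7, a_hf = 10, a_vlf = 12,
                            f_lf = 0.08, f_hf = 0.5,
                            jitter_sd = 3, artifact_rate = 0.01,
                            amp_mod_sd = 0.25,
                            n_subjects = 7L, subject_sd = 0.25,
                            drug = c("none", "atropine", "propranolol"),
                            drug_time = NULL, seed = 1L) {
  drug <- match.arg(drug)
  if (is.null(drug_time)) drug_time <- duration / 2
  cfg <- list(duration = duration, basal_hr = basal_hr, a_lf = a_lf,
              a_hf = a_hf, a_vlf = a_vlf,
              f_lf = f_lf, f_hf = f_hf, jitter_sd = jitter_sd,
              artifact_rate = artifact_rate, amp_mod_sd = amp_mod_sd,
              n_subjects = as.integer(n_subjects), subject_sd = subject_sd,
              drug = drug, drug_time = drug_time, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

#' @rdname scenario_config
#' @param config A `scenario_config` to validate.
#' @export
validate_scenario <- function(config) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(config$duration > 0, "duration must be positive")
  chk(config$basal_hr > 20 && config$basal_hr < 600,
      "basal_hr outside plausible range")
  chk(config$f_lf >= 0.04 && config$f_lf < 0.15,
      "f_lf must lie in [0.04, 0.15)")
  chk(config$f_hf >= 0.15, "f_hf must be >= 0.15")
  chk(config$a_lf >= 0 && config$a_hf >= 0 && config$a_vlf >= 0,
      "amplitudes must be >= 0")
  chk(config$artifact_rate >= 0 && config$artifact_rate <= 0.05,
      "artifact_rate must lie in [0, 0.05]")
  chk(config$jitter_sd >= 0, "jitter_sd must be >= 0")
  chk(config$amp_mod_sd >= 0, "amp_mod_sd must be >= 0")
  chk(config$subject_sd >= 0, "subject_sd must be >= 0")
  chk(config$n_subjects >= 1L, "n_subjects must be >= 1")
  chk(config$drug_time > 0 && config$drug_time < config$duration,
      "drug_time must fall inside the record")
  if (length(problems))
    stop("invalid scenario: ", paste(problems, collapse = "; "))
  invisible(config)
}

# deterministic per-subject seed derived from the master seed (kept < 2^31)
.subject_seed <- function(seed, subject) {
  (as.numeric(seed) * 100003 + subject * 7919) %% 2147483647
}

.drug_multipliers <- function(drug) {
  switch(drug,
    none = c(hr = 1, lf = 1, hf = 1),
    atropine = c(hr = 1.22, lf = 1, hf = 0.25),
    propranolol = c(hr = 0.91, lf = 0.35, hf = 1))
}

#' Generate one simulated subject
#'
#' Places beats iteratively on the instantaneous heart period
#' `r(t) = 60000 / hr(t) + a_lf(t) sin(2 pi f_lf t + phi1)
#'       + a_hf(t) sin(2 pi f_hf t + phi2) + jitter`,
#' with the next beat at `t + r(t) / 1000`. Subject-level basal rate and
#' amplitudes are drawn around the scenario values (relative SD
#' `subject_sd`); amplitudes additionally drift slowly over the record
#' (lognormal, 60-s knots, relative SD `amp_mod_sd`). After `drug_time`
#' the drug multipliers ramp in over a 30-s raised-cosine transition.
#' Detection artifacts are then injected: a missed beat deletes a beat
#' time (merging two intervals), a spurious detection inserts one
#' (splitting an interval).
#'
#' @param config A [scenario_config()].
#' @param subject Subject number (1-based); its seed derives
#'   deterministically from the master seed.
#' @return A [beat_series()] with all beats flagged `"valid"` (artifacts
#'   are present but unlabeled: finding them is the cleaner's job).
#' @export
generate_subject <- function(config, subject = 1L) {
  validate_scenario(config)
  set.seed(.subject_seed(config$seed, subject))
  sdev <- function(x) x * exp(rnorm(1L, 0, config$subject_sd) - config$subject_sd^2 / 2)
  hr0 <- sdev(config$basal_hr)
  alf0 <- sdev(config$a_lf)
  ahf0 <- sdev(config$a_hf)
  avlf0 <- sdev(config$a_vlf)
  phi <- runif(2L, 0, 2 * pi)
  # very-low-frequency wander: smooth Gaussian process, 25-s knots
  vknots <- seq(0, config$duration + 25, by = 25)
  vz <- rnorm(length(vknots), 0, avlf0)
  vlf <- function(t) approx(vknots, vz, xout = t, rule = 2)$y
  # slow behavioural-state drift: lognormal interpolated between 60-s knots
  knots <- seq(0, config$duration + 60, by = 60)
  logmod <- function() {
    z <- rnorm(length(knots), 0, config$amp_mod_sd)
    function(t) exp(approx(knots, z, xout = t, rule = 2)$y - config$amp_mod_sd^2 / 2)
  }
  mod_lf <- logmod(); mod_hf <- logmod()
  mult <- .drug_multipliers(config$drug)
  ramp <- function(t) {
    u <- pmin(pmax((t - config$drug_time) / 30, 0), 1)
    0.5 * (1 - cos(pi * u))
  }
  nmax <- ceiling(config$duration * config$basal_hr * 2 / 60) + 10L
  times <- numeric(nmax)
  t <- 0
  jit <- if (config$jitter_sd > 0) rnorm(nmax, 0, config$jitter_sd) else numeric(nmax)
  k <- 0L
  while (t < config$duration && k < nmax) {
    s <- ramp(t)
    hr_t <- hr0 * (1 + s * (mult["hr"] - 1))
    base <- 60000 / hr_t + vlf(t) +
      alf0 * mod_lf(t) * (1 + s * (mult["lf"] - 1)) * sin(2 * pi * config$f_lf * t + phi[1L]) +
      ahf0 * mod_hf(t) * (1 + s * (mult["hf"] - 1)) * sin(2 * pi * config$f_hf * t + phi[2L])
    if (base <= 0)
      stop("instantaneous heart period fell to zero: modulation amplitudes too large")
    k <- k + 1L
    rr <- max(base + jit[k], 120)
    t <- t + rr / 1000
    times[k] <- t
  }
  times <- .inject_artifacts(times[seq_len(k)], config$artifact_rate)
  rr <- diff(c(0, times)) * 1000
  beat_series(time_s = times, rr_ms = rr)
}

# detection artifacts on the beat-time vector: deletion = missed beat
# (intervals merge), insertion = spurious/ectopic detection (interval splits)
.inject_artifacts <- function(times, rate) {
  if (rate <= 0 || length(times) < 4L) return(times)
  n <- length(times)
  hit <- which(runif(n) < rate)
  hit <- hit[hit > 1L & hit < n]
  if (!length(hit)) return(times)
  type <- runif(length(hit)) < 0.5
  drop_idx <- hit[type]
  ins_at <- hit[!type]
  ins_times <- vapply(ins_at, function(i) {
    times[i - 1L] + runif(1L, 0.3, 0.7) * (times[i] - times[i - 1L])
  }, numeric(1))
  keep <- setdiff(seq_len(n), drop_idx)
  sort(c(times[keep], ins_times))
}

#' Generate a full cohort
#'
#' @param config A [scenario_config()].
#' @return A list of [beat_series()], one per subject, with a `manifest`
#'   attribute (data frame of subject number and seed).
#' @export
generate_cohort <- function(config) {
  validate_scenario(config)
  subjects <- seq_len(config$n_subjects)
  cohort <- lapply(subjects, function(s) generate_subject(config, s))
  attr(cohort, "manifest") <- data.frame(
    subject = subjects,
    seed = vapply(subjects, function(s) .subject_seed(config$seed, s), numeric(1)),
    n_beats = vapply(cohort, nrow, integer(1))
  )
  cohort
}

#' Analysis periods of a blockade experiment
#'
#' The two 5-minute analysis periods: 10 to 5 minutes before the
#' injection and 5 to 10 minutes after it. The +/- 5 min around the
#' injection is deliberately excluded so that the rapid drug-induced heart
#' rate transition never enters a window.
#'
#' @param drug_time Injection time, seconds.
#' @return List with `before = c(t0, t1)` and `after = c(t0, t1)`.
#' @export
experiment_periods <- function(drug_time) {
  list(before = c(drug_time - 600, drug_time - 300),
       after = c(drug_time + 300, drug_time + 600))
}

#' Run the full in-silico blockade experiment
#'
#' For every subject: generate the R-R series, clean it (artifact flagging
#' and interpolation), resample at 8 Hz, compute the FSI and spectral
#' traces, and average each index over the two 5-minute analysis periods;
#' RMSSD is computed per period on the cleaned beat series. Per-index
#' [paired_comparison()]s across subjects are then assembled.
#'
#' @param config A [scenario_config()] with `drug_time` at least 10 min
#'   from both record ends.
#' @param indices Which indices to analyze (default all five).
#' @return An object of class `fsi_experiment`: list with `comparisons`
#'   (named list of [paired_comparison()]), `period_means` (long data
#'   frame subject x index x period), `config` and `periods`. Subjects
#'   whose pipeline fails are dropped; fewer than 3 completers is an error.
#' @export
run_experiment <- function(config,
                           indices = c("fsi", "hf", "lf", "nhf", "rmssd")) {
  validate_scenario(config)
  per <- experiment_periods(config$drug_time)
  if (per$before[1L] < 0 || per$after[2L] > config$duration)
    stop("record too short: need >= 10 min on both sides of drug_time")
  rows <- list()
  completed <- 0L
  for (s in seq_len(config$n_subjects)) {
    res <- tryCatch(.subject_period_means(config, s, per, indices),
                    error = function(e) {
                      warning(sprintf("subject %d failed: %s", s, conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) next
    completed <- completed + 1L
    rows[[length(rows) + 1L]] <- res
  }
  if (completed < 3L)
    stop("fewer than 3 subjects completed the experiment")
  pm <- do.call(rbind, rows)
  comparisons <- lapply(indices, function(ix) {
    sub <- pm[pm$index == ix, ]
    wide <- merge(sub[sub$period == "before", c("subject", "value")],
                  sub[sub$period == "after", c("subject", "value")],
                  by = "subject", suffixes = c("_before", "_after"))
    paired_comparison(wide$value_before, wide$value_after, index = ix)
  })
  names(comparisons) <- indices
  structure(list(comparisons = comparisons, period_means = pm,
                 config = config, periods = per),
            class = "fsi_experiment")
}

.subject_period_means <- function(config, s, per, indices) {
  beats <- clean_beats(generate_subject(config, s))
  u <- resample_uniform(beats, rate = 8)
  traces <- list()
  if ("fsi" %in% indices) traces$fsi <- fsi_trace(u)
  if (any(c("hf", "lf", "nhf") %in% indices)) {
    st <- spectral_trace(u)
    for (b in intersect(indices, c("hf", "lf", "nhf")))
      traces[[b]] <- band_trace(st, b)
  }
  out <- list()
  for (ix in indices) {
    for (p in c("before", "after")) {
      v <- if (ix == "rmssd")
        rmssd(beats, per[[p]][1L], per[[p]][2L])
      else
        period_mean(traces[[ix]], per[[p]][1L], per[[p]][2L])
      out[[length(out) + 1L]] <- data.frame(
        subject = s, index = ix, period = p, value = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.fsi_experiment <- function(x, ...) {
  cat(sprintf("<fsi_experiment> drug=%s, n=%d subjects\n",
              x$config$drug, x$config$n_subjects))
  print(comparison_table(x$comparisons))
  invisible(x)
}

#' Adversarial window suite
#'
#' Generates a seeded suite of extreme 64-s analysis windows used to
#' stress-test the index's output bound: pure sinusoids with amplitudes
#' spanning 0.1-200 ms and frequencies 0.01-3.5 Hz, white noise of
#' matching amplitude range, sparse impulse trains, two-tone mixtures, and
#' constant (degenerate) windows, all riding on physiologic baselines.
#'
#' @param n Number of windows (default 500).
#' @param seed Seed.
#' @param n_samples Samples per window (default 512).
#' @param rate Sampling rate (default 8 Hz).
#' @return A numeric matrix, one window per row.
#' @export
adversarial_windows <- function(n = 500L, seed = 1L, n_samples = 512L, rate = 8) {
  set.seed(seed)
  t <- (seq_len(n_samples) - 1L) / rate
  kinds <- sample(c("sine", "noise", "impulse", "twotone", "constant"),
                  n, replace = TRUE, prob = c(0.35, 0.25, 0.15, 0.2, 0.05))
  out <- matrix(0, nrow = n, ncol = n_samples)
  ramp <- function() exp(runif(1L, log(0.1), log(200)))
  rfreq <- function() exp(runif(1L, log(0.01), log(3.5)))
  for (i in seq_len(n)) {
    base <- runif(1L, 300, 500)
    out[i, ] <- base + switch(kinds[i],
      sine = ramp() * sin(2 * pi * rfreq() * t + runif(1L, 0, 2 * pi)),
      noise = rnorm(n_samples, 0, ramp()),
      impulse = {
        x <- numeric(n_samples)
        idx <- sample(n_samples, sample(2:20, 1L))
        x[idx] <- sample(c(-1, 1), length(idx), TRUE) * ramp()
        x
      },
      twotone = ramp() * sin(2 * pi * rfreq() * t + runif(1L, 0, 2 * pi)) +
        ramp() * sin(2 * pi * rfreq() * t + runif(1L, 0, 2 * pi)),
      constant = 0)
  }
  out
}
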