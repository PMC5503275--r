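# fsindex

Fetal Stress Index and heart rate variability analysis in R.

## The problem

The high-frequency (HF, > 0.15 Hz) oscillations of the beat-to-beat R-R
interval series are driven by parasympathetic (vagal) modulation alone, so
their suppression is the expected signature of vagal withdrawal — in the
fetal setting, a candidate early marker of hypoxia and acidosis. Classic
HRV readouts (RMSSD, FFT band powers) track this physiology but inherit
each subject's basal heart rate, overall variability magnitude and
oscillation frequency, making their inter-subject dispersion too large for
clinical thresholds.

The **Fetal Stress Index (FSI)** is a 0–100 index built to strip those
nuisance factors out. Over each 64-s window of the 8 Hz resampled R-R
signal (`N = 512` samples):

1. mean-center: `M = mean(RR)`, `RR' = RR − M`;
2. normalize: `S = ||RR'||₂`, `RR'' = RR' / S` (unit norm ⇒ magnitude
   invariance);
3. high-pass with a 5-level Daubechies 4-tap discrete wavelet transform
   (approximation band 0–0.125 Hz zeroed, the nearest dyadic cutoff to the
   0.15 Hz HF edge);
4. form upper/lower envelopes through the local extrema, integrate the
   envelope gap over four 16-s quarters `A1..A4`, keep
   `AUCmin = min(A₁..A₄)`;
5. map linearly: `FSI = 100 (5.1 · AUCmin + 1.2) / 12.8`, clipped to
   `[0, 100]`.

The window slides at 1 Hz. The package also provides the comparators
(RMSSD; VLF/LF/HF band powers from a 256-s Bartlett-tapered FFT window;
normalized HF = HF/(HF+LF)), the paired statistics of blockade studies
(exact/asymptotic Wilcoxon signed-rank, paired Cohen's *d*, %CV, median
(Q1–Q3) summaries), a seeded generator of fetal-like R-R series with
atropine/propranolol scenarios, and a CLI.

## Worked example

Simulate one fetal sheep receiving atropine (vagal blockade) at t = 750 s,
clean and resample the record, and compare the index across the two 5-min
analysis periods:

```r
library(fsindex)

cfg   <- scenario_config(drug = "atropine")   # 25 min, atropine at 750 s
beats <- clean_beats(generate_subject(cfg, subject = 1))
u     <- resample_uniform(beats)              # 8 Hz grid
tr    <- fsi_trace(u)                         # 1 Hz FSI trace
per   <- experiment_periods(cfg$drug_time)

period_mean(tr, per$before[1], per$before[2])
#> [1] 61.31154
period_mean(tr, per$after[1], per$after[2])
#> [1] 25.04555
rmssd(beats, per$before[1], per$before[2])
#> [1] 9.514452
rmssd(beats, per$after[1], per$after[2])
#> [1] 4.416729
```

The FSI falls from ~61 to ~25 after vagal blockade, and RMSSD from ~9.5 to
~4.4 ms — the parasympathetic-withdrawal signature. A full seven-subject
cohort with the table of medians, %CV, Wilcoxon p and effect sizes:

```r
run_experiment(scenario_config(drug = "atropine"))
#> <fsi_experiment> drug=atropine, n=7 subjects
#>       index                before cv_before                  after ...
#> fsi     fsi    48.72 (47.5-60.72)      15.0    26.89 (25.56-27.58) ...
```

Inspect a single window (all intermediates are exposed, `plot()` works):

```r
fsi_window(u$values[1:512])
#> <fsi_window> FSI 64.05 (M 338.2 ms, S 189.45 ms, AUCmin 1.3723; A = 1.640, 1.600, 1.455, 1.372)
```

## Command line

```sh
Rscript -e 'fsindex::fsi_cli_main()' simulate \
    --scenario inst/extdata/atropine_scenario.yaml --out-dir cohort/
Rscript -e 'fsindex::fsi_cli_main()' compute \
    --input cohort/subject_01.csv --out-dir run1/ --periods 150,450,1050,1350
Rscript -e 'fsindex::fsi_cli_main()' experiment \
    --scenario inst/extdata/atropine_scenario.yaml --out-dir exp/
```

Input R-R files are CSV/TSV with header `time_s,rr_ms[,flag]`, or a bare
column of consecutive R-R intervals in ms. Every output directory receives
the resolved configuration and package version for provenance.

## Documentation

See `vignettes/fsi-methods.Rmd` for the model, its assumptions, what the
synthetic cohort does and does not emulate, and every numerical
convention (integration rule, wavelet boundary handling, quantile type,
tie handling).
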