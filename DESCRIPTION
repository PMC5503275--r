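Package: fsindex
Title: Fetal Stress Index and Heart Rate Variability Analysis
Version: 0.1.0
Authors@R: person("fsindex", "developers", email = "fsindex@example.org",
    role = c("aut", "cre"))
Description: Computes the Fetal Stress Index (FSI), a 0-100 index of
    parasympathetic (vagal) cardiac modulation obtained from beat-to-beat
    R-R interval series by windowed mean-centering and Euclidean
    normalization, Daubechies 4-tap wavelet high-pass filtering, and
    measurement of the area enclosed by the signal envelopes. Also provides
    the classic heart-rate-variability comparators (RMSSD, VLF/LF/HF band
    powers from a Bartlett-tapered FFT, normalized HF), paired
    before/after statistics (exact and asymptotic Wilcoxon signed-rank,
    paired Cohen's d, coefficient of variation, median and quartile
    summaries), a seeded generator of fetal-like R-R series with
    low-frequency and high-frequency autonomic modulation and
    pharmacological-blockade scenarios (atropine, propranolol), and a
    command-line pipeline tying preprocessing, index computation and
    cohort experiments together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
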