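Package: stresshrv
Title: Acute-Stress ECG/HRV Analysis Pipeline with a Synthetic Study Generator
Version: 0.1.0
Authors@R:
    person("stresshrv", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for acute-stress psychophysiology studies built
    on single-lead ECG: Pan-Tompkins style R-peak detection, physiological
    validity filtering of RR intervals into NN series, linear time- and
    frequency-domain heart rate variability features (AVNN, SDNN, RMSSD,
    pNNx, LF/HF via Lomb-Scargle or resampled Welch spectra) on
    event-synchronised 5-minute blocks, choice-reaction-time task scoring,
    and nonparametric repeated-measures group statistics (exact Friedman,
    Wilcoxon signed-rank and Spearman tests with brute-force-verified null
    distributions). Includes an integral pulse frequency modulation (IPFM)
    simulator that generates full synthetic cohorts (ECG/RR, protocol events,
    reaction-time logs, questionnaire scores) with known ground truth, so the
    whole pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
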