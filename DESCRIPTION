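Package: illusioneeg
Title: Continuous-Design Auditory Signal Detection EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG experiments on experimentally induced
    auditory illusions in a continuous signal-detection design. Provides
    speech-shaped-noise stimulus construction, adaptive staircase and hearing
    level threshold procedures run against simulated observers, signal
    detection theory categorization of continuous event streams into hits,
    misses, false alarms and correct rejections, windowed-sinc FIR filtering
    and epoching, event-related potential component analysis, Morlet wavelet
    event-related spectral perturbations with frequency-dependent baseline
    margins, nonparametric cluster-based permutation statistics, and a
    seeded synthetic multi-subject EEG generator with full ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
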