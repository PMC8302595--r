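Package: epiphase
Title: Quantification of Optogenetically Induced Epileptiform Activity and
    Calcium-ECoG Phase Locking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic seizure-induction experiments
    combining electrocorticography (ECoG), single-unit recordings and in vivo
    calcium imaging. Provides ECoG band-power estimation with Blackman-windowed
    FFTs and complex Morlet wavelet theta tracking, threshold-based detection
    of epileptiform peaks and episode characterization (onset delay, duration,
    modified Racine scale encoding), a peak-triggered-average phase-locking
    statistic for calcium traces with a shuffled-surrogate null distribution
    and z-score decision rule, per-trial spike-train metrics (PSTH,
    responsiveness), input resistance from I-V data, and a behavioral
    discrimination index. Includes a synthetic-data generator with known
    ground truth (1/f ECoG baseline with theta-band epileptiform peak trains,
    coupled GCaMP-like calcium transients, Poisson spike trains) so the whole
    pipeline can be validated without access to in vivo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
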