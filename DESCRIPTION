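Package: mmnkit
Title: Auditory Mismatch Negativity Paradigms, Synthetic EEG and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for auditory mismatch-negativity (MMN) studies based on the
    multifeature oddball paradigm: synthesis of standard and deviant tone-complex
    stimuli, pseudo-randomized block sequencing with event scheduling, forward
    simulation of multichannel EEG with group-dependent MMN components and
    realistic background activity, preprocessing (band-pass filtering, ocular
    artifact removal, epoching, amplitude-based rejection), difference-wave ERP
    analysis over a frontocentral region of interest with mastoid polarity-reversal
    validation, extraction of MMN amplitude, latency and area under the curve, and
    the full group-statistics battery (one-way and repeated-measures ANOVA, Tukey
    and Bonferroni post hoc tests, rank tests, and summary-statistic forms).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
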