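Package: samph
Title: Spectral Amplitude Modulation Phase Hierarchy Analysis of Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temporal modulation structure of recorded
    speech. Implements the two-stage Spectral Amplitude Modulation Phase
    Hierarchy (S-AMPH) decomposition (five-band spectral FIR filterbank,
    Hilbert envelope extraction, downsampling, and a second filterbank
    isolating delta, theta and beta/low-gamma rate amplitude modulations), the
    24-channel log-spaced envelope modulation spectrum with per-band energy
    (area under the curve), and the n:m Phase Synchronisation Index between
    nested amplitude-modulation bands, together with cohort-level statistics
    (MANOVA, repeated-measures ANOVA, Tukey post hocs, rank correlations,
    non-parametric group tests) and a synthetic speech-like signal generator
    with ground-truth phase coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
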