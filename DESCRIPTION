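Package: cngrectify
Title: Decomposition of Ionic Rectification in CNG Channels from
    Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for dissecting rectification of cyclic
    nucleotide-gated (CNGA1) channel currents into an open-pore component
    (voltage-dependent single-channel conductance) and a gating component
    (voltage-dependent open probability).  Implements isochronal
    tail-current analysis, two-component Boltzmann activation fitting with
    gating-charge conversion, stationary noise analysis
    (variance-to-mean), channel counting from macroscopic currents,
    gating-current charge integration and detectability mapping, together
    with a seeded synthetic patch-clamp generator (macroscopic,
    single-channel and gating-current sweeps) so that every stage of the
    pipeline can be exercised and validated without access to raw
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    mclust,
    pracma,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
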