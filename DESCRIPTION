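Package: optoerg
Title: Analysis of Mixed Native and Optogenetic ERG and VEP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting electroretinogram (ERG) and visually evoked
    potential (VEP) recordings from retinas that carry both native
    photoreceptor responses and optogenetic (ReaChR-driven) responses.
    Provides zero-phase band-pass and mains-notch filtering, trial averaging,
    deterministic wave-marker placement under adaptation-specific measurement
    conventions (a, b, P1, N1, and the optogenetic a_o and N1_o components),
    discrete-Fourier analysis of oscillatory potentials, photometric
    conversion between flash energy and retinal photon flux with
    classification against the ReaChR activation threshold, a parametric
    waveform simulator with genotype templates (wild-type, ReaChR-expressing,
    and retina-degenerate ReaChR-expressing), and the accompanying
    summary and inferential statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
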