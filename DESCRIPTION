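Package: sram
Title: Syllable-Rate-Adjusted Modulation Metrics for Speech Intelligibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective speech-intelligibility metrics built on the envelope
    modulation spectrum: an octave-band Butterworth filterbank with Hilbert
    intensity envelopes, Bartlett-averaged modulation power spectra, the
    total modulation power (TMP) and syllable-rate-adjusted modulation
    (SRAM) indices, acoustic syllable-rate estimation from sub-band envelope
    correlation, psychometric (speech reception threshold) and
    metric-to-intelligibility transformation fitting, speech-spectrum-shaped
    noise synthesis and SNR mixing, plus deterministic synthetic speech-like
    fixtures so the whole pipeline is testable without recorded speech.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
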