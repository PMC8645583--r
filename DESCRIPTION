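Package: hmdeeg
Title: Signal-Quality Benchmarking of EEG Recordings During Head-Mounted
    Display Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A structured benchmark for testing whether a virtual-reality
    head-mounted display degrades the quality of concurrent EEG recordings.
    Implements a frequency-domain branch (eyes-open versus eyes-closed
    spectral analysis with mass-univariate Wilcoxon rank-sum testing and
    Benjamini-Hochberg false-discovery-rate control) and a time-domain
    branch (median-nerve somatosensory evoked potential component analysis
    at C6/CP4 with an interquartile-range based signal-to-noise statistic),
    together with a synthetic multichannel EEG session simulator (1/f
    background, eye-state dependent occipital alpha, mains interference,
    and headset-specific artifact line profiles) so the full pipeline is
    testable without recorded data.  Recordings are read and written as
    EDF files with plain-text sidecar event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
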