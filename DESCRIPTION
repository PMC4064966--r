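Package: stftcsp
Title: Single-Channel Motor-Imagery EEG Classification via Spectrogram
    Common Spatial Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies four-class motor imagery (left hand, right hand,
    foot, tongue) from a single EEG channel.  A short-time Fourier
    transform expands the one-channel signal into a frequency-by-time
    magnitude spectrogram whose frequency bins act as virtual channels;
    one-versus-rest common spatial patterns (CSP) extract per-class
    variance features from the 8-30 Hz band, and a radial-basis support
    vector classifier with grid-searched (C, gamma) and repeated
    stratified cross-validation scores the result.  Includes a synthetic
    generator of single-channel motor-imagery EEG (1/f background plus
    event-related mu/beta band-power modulation), trial epoching with
    artifact exclusion, an electrode-by-time-window evaluation grid with
    two-way ANOVA, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
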