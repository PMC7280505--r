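Package: nvcwave
Title: Neurovascular Coupling from Amplitude-Integrated EEG and NIRS by
    Wavelet Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw neonatal EEG to amplitude-integrated EEG (aEEG)
    margin traces with two independently specified algorithms, ingests
    device-computed aEEG, quantifies neurovascular coupling between the
    aEEG bandwidth and cerebral tissue oxygen saturation (SctO2) by
    Morlet wavelet transform coherence with AR(1)-surrogate significance
    testing and cone-of-influence masking, and assesses cross-algorithm
    agreement with coefficient-of-variation and Bland-Altman statistics.
    Includes a synthetic-recording generator with controllable coupling
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
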