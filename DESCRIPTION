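Package: neuroxtalk
Title: Lumped-Element Crosstalk Modeling and Back-Correction for
    Multichannel Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models electrical crosstalk along the brain-to-amplifier
    recording chain of high-density neural implants as a lumped-element
    transmission network, parametrizes the network from electrochemical
    impedance spectra (Randles and parallel-RC fits, access resistance,
    Newman disk spread resistance), and solves the resulting two-line and
    four-line circuits in the frequency domain to obtain active-to-passive
    transfer functions. Provides a per-frequency back-correction of the
    four-channel mixing system to recover crosstalk-free signals, a signal
    quality-control battery (Butterworth band splitting, Pearson
    correlation, Welch magnitude-squared coherence, amplitude-threshold
    spike detection, peri-stimulus time histograms, cross-correlograms),
    a routing-layout audit that discriminates crosstalk from volume
    conduction, and a synthetic electrocorticography generator with
    point sources under volume conduction on a 4x4 epicortical grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
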