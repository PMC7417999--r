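Package: optophys
Title: Simulation and Analysis of In Vivo Opto-Physiology Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying in vivo neurophysiology recordings around a
    pharmacological or optogenetic manipulation: fiber-photometry dF/F
    normalization with a sliding baseline and calcium-transient detection,
    firing-rate binning and potentiated/depressed/non-modulated unit
    classification with Bonferroni-corrected paired testing, opto-evoked local
    field potential peak-to-peak quantification and wire-responsiveness
    screening, Bartlett-tapered band-power spectra, open-field locomotion
    metrics, and stimulation-protocol builders (test pulses, LFS, TBS, HFS).
    A synthetic-session generator with known ground truth makes every stage
    testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
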