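Package: rgplan
Title: Receiver-Gain Calibration and SNR-Optimal Acquisition Planning for NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating the signal-to-noise ratio of an NMR
    receive chain as a function of receiver gain (RG), and for planning
    acquisitions that maximize SNR under the ADC-overflow constraint.
    Builds empirical SNR(RG) calibration curves from RG-sweep spectra,
    detects abrupt level-plan noise discontinuities, scales reference
    curves to arbitrary flip angle, polarization and spin concentration,
    and solves the constrained flip-angle/gain maximization on a grid.
    Includes spectral quantification (peak integration, noise RMS,
    clipping detection, ADC-ceiling estimation) and a receiver-chain
    simulator (gain, staged noise with level-plan switching, hard
    clipping, hyperpolarized decay series) so the whole workflow is
    testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
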