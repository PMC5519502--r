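Package: fmrsglu
Title: Simulation and Analysis of Combined fMRI-MRS Glutamate Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional magnetic resonance spectroscopy (fMRS)
    experiments in which proton spectra and a BOLD-fMRI signal are acquired
    concurrently from the same voxel during a block-design task. Provides a
    synthetic-data generator for semi-LASER-like short-TE spectra at 7 T with
    a hemodynamic-response-convolved BOLD series; a spectral preprocessing
    chain (eddy-current correction against an unsuppressed water reference,
    frequency alignment to the NAA singlet, least-squares phase correction,
    block-wise data reduction and binning); linear-combination model fitting
    of metabolite amplitudes with Cramer-Rao lower bounds, water-referenced
    institutional units and CSF correction; estimation and correction of
    BOLD-induced spectral line narrowing from the total-creatine singlet; and
    condition contrasts, difference spectra, glutamate time courses and
    glutamate-BOLD correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
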