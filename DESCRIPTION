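Package: ecgsoo
Title: Site-of-Origin Classification of Outflow-Tract Ventricular
    Arrhythmias from 12-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the ventricular chamber of origin (left
    versus right outflow tract) of outflow-tract ventricular arrhythmias
    from single 12-lead QRS complexes. Provides a controllable synthetic
    beat generator with a factorial anatomy x site-of-origin x electrode
    placement design, wavelet-based QRS delineation and fiducial
    detection, max-abs normalization and bin-mean downsampling, a full
    signal/wavelet/spectral feature battery with within-group lead
    comparisons, mixup data augmentation with an anatomical neighbor
    constraint and Beta-distributed sample weights, and support vector
    machine training and evaluation under simulated-only, clinical-only
    and hybrid scenarios, including exhaustive lead-subset search,
    extra-trees feature ranking and principal-component variance
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    kernlab,
    ranger,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
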