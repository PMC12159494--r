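Package: fuswaves
Title: Vasomotor Oscillations and Travelling Haemodynamic Waves in
    Functional Ultrasound Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of mesoscale cerebral-blood-volume movies acquired by
    functional ultrasound (Power Doppler) imaging. Detects and quantifies
    ~0.1 Hz vasomotor oscillations and travelling haemodynamic waves:
    band-amplitude (fALFF) mapping, static and sliding-window dynamic
    functional connectivity, group-mean-covariance principal component
    "oscillatory mode" analysis, spatiotemporal event detection with
    delay-map based trajectory pattern classification, and stimulation-block
    response extraction. Includes a ground-truthed synthetic vasomotion
    movie generator so that every stage of the pipeline can be validated
    by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    tiff,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
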