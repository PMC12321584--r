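Package: vesiclezone
Title: Synaptic Vesicle Replacement-Zone Morphometry and Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for presynaptic vesicle organization and
    function around the active zone. Implements 2D STED punctum morphometry
    (Gaussian pre-smoothing, two-pass blind Richardson-Lucy deconvolution,
    local-maxima punctum detection, half-intensity boundary contours, midline
    fitting and midline/midpoint distance quantification), electron-microscopy
    vesicle morphometry (docked/undocked classification, edge distances to the
    active-zone membrane, 2-nm binned distance histograms over 2-50 nm,
    replacement-zone counts within 20 nm, pit counting), fluorescence
    time-series analysis (rolling-ball background subtraction, dF/F, peak and
    paired-pulse-ratio extraction with decay correction, FRAP one-phase
    association fitting, coefficient-of-variation dispersion metrics,
    activity-driven dispersion time courses), fEPSP train analysis
    (normalization, window averages, readily-releasable-pool estimation by
    linear back-extrapolation of cumulative responses, recovery curves), group
    statistics (t, Mann-Whitney, Kruskal-Wallis with Dunn's post hoc), and
    synthetic-data generators with planted ground truth for every modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
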