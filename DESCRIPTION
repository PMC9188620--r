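Package: asltilab
Title: Inversion-Time Effects in Pulsed Arterial Spin Labeling: Simulation and Regional Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsed arterial spin labeling (PASL) acquisitions at multiple
    inversion times from ground-truth digital brain phantoms with configurable cerebral
    blood flow, arterial transit time and intravascular arterial blood volume; quantifies
    absolute CBF with the standard single-compartment bolus model; and analyses the
    region-dependent inversion-time effect between proximal and distal arterial
    territories via volume-of-interest and voxel-wise Z-score statistics, subtraction
    maps, and paired nonparametric testing with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
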