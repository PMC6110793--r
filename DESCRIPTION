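Package: benthospec
Title: In Situ Taxonomic Analysis of Benthic Megafauna from Underwater
    Hyperspectral Imagery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying benthic megafauna and sediment anomalies
    in underwater hyperspectral imagery (UHI). Provides an ENVI-style
    hyperspectral cube container with readers and writers, conversion of raw
    cubes to smoothed pseudo-reflectance (spectral subsetting,
    reference-spectrum division, moving-average smoothing), reference
    spectral libraries of optical fingerprints built from annotated regions
    of interest, spectral contrast angle matching for assigning unknown
    objects to known categories, supervised per-pixel classification with a
    support vector machine, connected-component detection of objects of
    interest with majority-vote labelling and density summaries, and a
    synthetic seafloor-scene generator with ground truth so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    e1071,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
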