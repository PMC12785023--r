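Package: msimargin
Title: Tumor Margin Delineation and Heterogeneity Mapping from Imaging
    Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for low-mass-range MALDI imaging mass spectrometry (MSI)
    of tissue sections: reading and writing imzML datacubes, total-ion-current
    normalization and mass-range windowing, exact single-linkage hierarchical
    segmentation of pixel spectra into binary and denary class images, a
    region-of-interest tumor-margin recognition statistic with exact binomial
    inference, a compressed-PNG-size information-content metric with
    regression trend tests, mass-tolerance metabolite annotation against a
    local formula table, and a ground-truthed synthetic phantom generator for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    xml2,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
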