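Package: msical
Title: Microsatellite Instability Calling from Capillary Electrophoresis Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic microsatellite instability (MSI) calling for
    tumour/matched-normal fragment-analysis data on the Bethesda/NCI
    five-marker panel (BAT-25, BAT-26, D5S346, D2S123, D17S250). Reads peak
    tables exported from a capillary gel electrophoresis fragment analyser,
    detects tumour-specific novel peaks against the matched normal with a
    configurable noise filter, computes per-marker percentage allelic
    variability, and classifies samples as MSS, MSI-L or MSI-H both by the
    traditional NCI unstable-marker count and by an MSI score based on total
    allelic variability. Includes concordance analysis against
    immunohistochemistry labels, a seed-controlled synthetic electropherogram
    simulator with stutter ladders and tumour-fraction dilution series, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    withr,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
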