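Package: habiq
Title: Habitat Quality Assessment, Land-Use Change Metrics and Geographical
    Detector Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assess landscape habitat quality from categorical land-use rasters
    with a threat distance-decay degradation model and half-saturation quality
    transform, quantify land-use change between epochs with transfer matrices
    and single/integrated dynamic degrees, and attribute spatial heterogeneity
    of zonal responses with geographical-detector statistics (factor q with
    permutation or noncentral-F significance, interaction detection, ecological
    F test). Includes a synthetic-landscape and zonal-table generator with
    known ground truth so the whole chain is testable end to end, readers and
    writers for ESRI ASCII grid rasters and the tabular interchange formats,
    ggplot2 visualisations, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
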