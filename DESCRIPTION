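Package: hoodspot
Title: Neighbourhood Hot-Spot Analysis of Pneumonia-Associated Hospitalisations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area spatial epidemiology of hospital discharge data.
    Classifies ICD-9-CM discharge records into non-severe and severe
    pneumonia-associated hospitalisations, computes direct age-standardised
    neighbourhood rates per 100,000, estimates the range of spatial
    autocorrelation by semivariogram modelling with weighted least squares,
    validates it with an incremental global Moran's I profile, detects hot and
    cold spots with local Moran's I under conditional permutation inference,
    and compares patient characteristics between hot and cold spots. Includes
    a synthetic discharge-data generator with a programmed spatially
    autocorrelated rate surface so the whole pipeline can be exercised and
    validated without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
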