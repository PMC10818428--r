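Package: reyrisk
Title: Ecological and Health Risk Assessment of Rare Earth Elements and
    Heavy Metals in Coal Ash
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the ecological and human health risks posed
    by rare earth elements plus yttrium (REYs) and heavy metal(loid)s in coal
    fly ash and bottom ash. Implements geochemical normalization against
    crustal and shale reference compositions, cerium and europium anomaly
    calculation, resource-prospectivity metrics (critical-REY percentage and
    outlook coefficient), enrichment factor, geoaccumulation index, the
    Hakanson potential ecological risk index, the USEPA residential-soil
    multi-pathway exposure model (hazard quotient/index and cancer risk for
    child and adult receptors), and Monte Carlo uncertainty propagation with
    rank-correlation sensitivity analysis. Ships reference tables (UCC and
    NASC compositions, toxicity response coefficients, reference doses and
    cancer slope factors) and a synthetic concentration-table generator with
    a single-factor inter-element correlation structure for testing complete
    analysis pipelines without access to raw laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
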