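Package: pvdc
Title: Vascular Bioactivity Scoring and Toxicity Signatures from
    High-Throughput Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for prioritizing chemicals as putative vascular
    disruptor compounds (pVDCs) from high-throughput screening potency
    data (AC50/LEC). Computes weighted vascular bioactivity scores over
    a configurable panel of vascular target features, renders ToxPi-style
    radial profiles, derives chemical-pathway perturbation scores from
    assay-to-gene-to-pathway mappings, models prenatal developmental
    endpoint records with species-specific positive sets, and builds
    two-class toxicity signatures by forward stepwise linear discriminant
    analysis with stratified cross-validation (balanced accuracy,
    sensitivity, specificity, AUC). Includes a synthetic-data generator
    with planted structure for end-to-end validation and a literature
    co-occurrence target ranking utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    fgsea,
    optparse
Config/testthat/edition: 3
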