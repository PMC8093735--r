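Package: gutshift
Title: Gut-Content Diet Analysis and Ontogenetic Niche-Shift Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of fish gut-content data:
    diet-importance metrics (frequency of occurrence, percentage biomass,
    index of relative importance, gut fullness), trophic niche breadth
    (Levins, Simpson, Shannon and their evenness forms) and diet overlap
    (Schoener, Horn) with jackknife uncertainty, permutation-based
    community comparison (ANOSIM on Bray-Curtis dissimilarity, SIMPER
    decomposition), and ontogeny classification via Ward clustering and
    two-group canonical discriminant analysis. Includes a calibrated
    synthetic cohort generator emulating a two-size-class weatherfish
    (Misgurnus fossilis) diet study, so every stage of the pipeline can be
    exercised and tested without access to the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
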