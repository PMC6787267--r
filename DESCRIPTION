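Package: ecoassembly
Title: Null-Model Quantification of Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes structuring microbial
    community turnover along environmental gradients. Implements
    abundance-weighted beta mean-nearest-taxon distance (betaMNTD), the
    tip-shuffling null model and beta nearest taxon index (betaNTI), the
    Bray-Curtis-based Raup-Crick index (RCbray), and the five-way
    classification of pairwise turnover into variable selection,
    homogenizing selection, dispersal limitation, homogenizing dispersal
    and drift, with per-group and between-group contribution rates.
    Also provides rarefaction, alpha/beta diversity, distance-decay
    regression, Anosim/Mantel/partial-Mantel permutation statistics, and
    a synthetic-community generator with known assembly regimes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    biomformat
Config/testthat/edition: 3
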