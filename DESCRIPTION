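Package: pesol
Title: Sequence Determinants of Protein Expression and Solubility in E. coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale statistical analysis of the amino-acid
    determinants of recombinant protein expression level (E) and solubility
    score (S) in Escherichia coli. Computes composition-based sequence
    parameters (per-residue fractions with buried/exposed splits, GRAVY,
    side-chain entropy, charge metrics, isoelectric point, disorder fraction,
    rare-codon splits), fits binary and proportional-odds ordinal logistic
    regressions by maximum likelihood with Wald, likelihood-ratio and AIC
    machinery, runs the single-regression screening, variable-culling,
    stepwise-selection and AIC-pruning pipeline, builds the pES usability
    predictor with calibration curves and cutoff trade-off tables, and
    simulates synthetic cohorts with the statistical structure of
    high-throughput expression screens for end-to-end testing and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
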