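Package: oncoflux
Title: Oncometabolite Prediction from Context-Specific Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that predicts candidate oncometabolites from
    somatic mutation tables and paired cancer/normal expression matrices.
    Recurrently mutated metabolic enzymes are screened (recurrence, mutation-class
    arms, isoenzyme redundancy, functional-impact score), context-specific
    genome-scale metabolic models are extracted with a GIMME-style algorithm,
    loss-of-function oncometabolites are called by differential hit-and-run flux
    sampling of enzyme-deficient models, and gain-of-function oncometabolite
    substructures are enumerated by chemoinformatic reaction-operator promiscuity
    with fingerprint Tanimoto screening and maximum-common-substructure summaries.
    Includes a synthetic-data generator with planted ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    boot,
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
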