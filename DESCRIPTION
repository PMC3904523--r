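Package: csmpred
Title: Graph-Based Structural Signatures for Predicting Mutation Effects on
    Protein Stability and Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes cutoff-scanning-matrix (CSM) structural signatures for
    single-point missense mutations from wild-type protein structures in PDB
    format. A signature encodes the cumulative distribution of inter-atomic
    distances in the residue environment around the mutation site, segmented
    by atom pharmacophore classes, together with a pharmacophore-change
    vector and experimental conditions (pH, temperature, relative solvent
    accessibility). Signatures train Gaussian-process regression and
    classification models that predict changes in Gibbs free energy of
    folding or of binding. Includes parsers for ProTherm-, SKEMPI- and
    ProNIT-style thermodynamic tables, free-energy conversion of
    dissociation constants, cross-validation protocols with low-redundancy
    (per-protein, per-position) grouping, evaluation metrics, and
    deterministic synthetic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
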