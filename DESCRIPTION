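Package: ionstate
Title: Rule-Based Enumeration of Small-Molecule Ionization States over a pH Range
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the major ionization states (protomers) of drug-like
    small molecules for a user-specified pH range, for virtual-screening
    library preparation. Ionizable sites are located by prioritized SMARTS
    substructure matching with atom masking, each moiety carries an empirical
    pKa interval [mu - n*sigma, mu + n*sigma], and an interval-overlap rule
    decides whether a site is emitted protonated, deprotonated, or both,
    including three-state handling of phosphates and phosphonates. Also
    provides Henderson-Hasselbalch ionization fractions, an accuracy
    evaluation harness (correct/excess/incorrect outcome taxonomy, pKa
    precision-factor sweeps, per-moiety threefold cross-validation), dataset
    curation filters, and seeded synthetic fixture generators. Low-level
    molecule handling is performed by RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (or set via options(ionstate.python = ...))
Config/testthat/edition: 3
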