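Package: SERSscreen
Title: Rapid SERS-Based Screening of Benzoic Acid Residues in Food Extracts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for rapid surface-enhanced Raman scattering (SERS)
    screening of benzoic acid (BA) preservative residues in food extracts.
    Implements adaptive iteratively reweighted penalized least-squares
    (AirPLS) baseline correction built on a sparse Whittaker smoother,
    per-spectrum Z-score standardisation with band-interval Z-ratio scoring
    of the BA monomer and dimer marker bands, the "Rule 5" high-risk
    triage classifier, empirical ROC/AUC and Pearson evaluation against
    reference HPLC concentrations, seeded bootstrap triage-risk simulation,
    and a synthetic SERS spectrum generator with known ground truth for
    end-to-end validation. Ships the published 40-sample screening cohort
    as a checksummed plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-io.R'
    'baseline.R'
    'scoring.R'
    'evaluation.R'
    'synthetic.R'
    'table2.R'
    'pipeline.R'
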